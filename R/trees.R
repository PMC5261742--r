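.apomacc <- new.env(parent = emptyenv())

#' All 15 labeled five-taxon topologies rooted by the outgroup
#'
#' Enumerates every unrooted binary tree on the labeled tips A1, A2 (apomict
#' haplotypes), S1, S2 (sexual pseudo-haplotypes) and OUT (outgroup), oriented
#' away from the internal node adjacent to OUT (the root). The enumeration
#' order is the canonical topology index used for deterministic tie-breaks.
#'
#' @return list of 15 topology descriptions: `id`, postorder `parent`/`child`
#'   edge vectors (tips are nodes 1..5 in TAXA order, internal nodes 6..8,
#'   `root` adjacent to OUT), `tipset` (tips below each edge) and `splits`
#'   (non-trivial bipartitions, as sorted tip-id strings).
#' @export
topologies5 <- function() {
  if (!is.null(.apomacc$topologies)) return(.apomacc$topologies)
  insert_tip <- function(edges, tip, newnode)
    lapply(seq_len(nrow(edges)), function(i)
      rbind(edges[-i, , drop = FALSE],
            c(edges[i, 1], newnode), c(newnode, edges[i, 2]),
            c(newnode, tip)))
  base <- matrix(c(6L, 1L, 6L, 2L, 6L, 3L), ncol = 2, byrow = TRUE)
  t4 <- insert_tip(base, 4L, 7L)
  t5 <- unlist(lapply(t4, insert_tip, tip = 5L, newnode = 8L),
               recursive = FALSE)
  .apomacc$topologies <- lapply(seq_along(t5), function(i)
    orient_topology(t5[[i]], i))
  .apomacc$topologies
}

orient_topology <- function(edges, id) {
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(seq_len(max(nodes)), function(n)
    sort(unique(c(edges[edges[, 1] == n, 2], edges[edges[, 2] == n, 1]))))
  root <- adj[[5L]]          # internal node adjacent to OUT
  stopifnot(length(root) == 1)
  parent <- child <- integer(0)
  visit <- function(node, par) {
    for (nb in adj[[node]]) if (nb != par) {
      visit(nb, node)
      parent <<- c(parent, node)
      child <<- c(child, nb)
    }
  }
  visit(root, 0L)
  tipset <- lapply(seq_along(child), function(e) {
    below <- child[e]
    repeat {
      kids <- child[parent %in% below & !child %in% below]
      if (length(kids) == 0) break
      below <- c(below, kids)
    }
    sort(below[below <= 5L])
  })
  children_of <- split(child, factor(parent, levels = seq_len(max(nodes))))
  internal <- child[child > 5L]
  splits <- vapply(which(child > 5L), function(e)
    paste(tipset[[e]], collapse = ","), "")
  list(id = id, parent = parent, child = child, root = root,
       tipset = tipset, children_of = children_of, splits = splits)
}

resolve_topology <- function(topology) {
  if (inherits(topology, "tree_result")) topology <- topology$topology
  if (is.numeric(topology) && length(topology) == 1 &&
      topology >= 1 && topology <= 15)
    return(topologies5()[[as.integer(topology)]])
  stop("topology must be an index 1..15 or a tree_result")
}

#' Fit the maximum-likelihood five-taxon tree under GTR+Gamma
#'
#' Evaluates all 15 outgroup-rooted topologies exhaustively (5 taxa make
#' heuristic search unnecessary). Base frequencies are set to the empirical
#' alignment frequencies; the Gamma shape alpha is estimated once per
#' alignment by a 1-D search on the provisional best topology, after which all
#' topologies are refit. Branch lengths are optimized per topology by
#' coordinate-wise Brent search (convergence tolerance `tol`). Ties are broken
#' deterministically by canonical topology index.
#'
#' @param aln A [assemble_alignment()] result.
#' @param model optional [substitution_model()] to fix the model (skips
#'   alpha/pi estimation).
#' @param control list: `estimate_alpha` (default TRUE), `k` (4), `init_alpha`
#'   (1), `tol` (1e-6), `max_sweeps` (20), `brent_tol` (1e-4),
#'   `min_columns` (500): alignments shorter than this are flagged
#'   `pass_length = FALSE`.
#' @return list of class `tree_result`: `topology` (canonical index),
#'   `parent`/`child`/`lengths` (postorder edges), `loglik`, `all_loglik`
#'   (all 15 optima), `model`, `converged`, `s_divergence` (S1-S2 difference
#'   proportion, used by [filter_trees()]), `n_columns`, `region`,
#'   `supports` (`NULL` until [bootstrap_support()]).
#' @export
fit_ml_tree <- function(aln, model = NULL, control = list()) {
  ctl <- modifyList(list(estimate_alpha = TRUE, k = 4, init_alpha = 1,
                         tol = 1e-6, max_sweeps = 20, brent_tol = 1e-4,
                         scan_tol = 1e-2, scan_sweeps = 4, scan_brent = 3e-3,
                         min_columns = 500), control)
  pat <- aln_patterns(aln)
  if (sum(pat$weights) < 1) stop("alignment has no usable columns")
  if (is.null(model)) {
    tabb <- tabulate(match(aln$seqs, BASES), nbins = 4)
    pi <- (tabb + 1) / (sum(tabb) + 4)
    model <- substitution_model(pi = pi, alpha = ctl$init_alpha, k = ctl$k)
    estimate_alpha <- isTRUE(ctl$estimate_alpha)
  } else estimate_alpha <- FALSE

  tset <- topologies5()
  parents <- vapply(tset, `[[`, integer(7), "parent")
  childs <- vapply(tset, `[[`, integer(7), "child")
  roots <- vapply(tset, `[[`, 0L, "root")
  init <- rep(0.02, 7)
  # fast scan of all topologies, then full-tolerance refinement of the winner
  scan <- function(model)
    cpp_fit_topologies(pat$tips, pat$weights, parents, childs, roots, init,
                       model$pi, model$V, model$Vinv, model$lambda,
                       model$rates, ctl$scan_tol, ctl$scan_sweeps,
                       ctl$scan_brent)
  fits <- scan(model)
  best <- which.max(fits$loglik)   # first maximum = lowest canonical index
  if (estimate_alpha) {
    topo <- tset[[best]]
    blen <- fits$lengths[, best]
    opt <- optimize(function(a) {
      m <- substitution_model(pi = model$pi, alpha = a, k = ctl$k)
      cpp_loglik(pat$tips, pat$weights, topo$parent, topo$child, blen,
                 topo$root, m$pi, m$V, m$Vinv, m$lambda, m$rates)
    }, interval = c(0.05, 50), maximum = TRUE, tol = 0.05)
    model <- substitution_model(pi = model$pi, alpha = opt$maximum, k = ctl$k)
    fits <- scan(model)
    best <- which.max(fits$loglik)
  }
  topo <- tset[[best]]
  refined <- cpp_fit_branch_lengths(pat$tips, pat$weights, topo$parent,
                                    topo$child, fits$lengths[, best],
                                    topo$root, model$pi, model$V, model$Vinv,
                                    model$lambda, model$rates, ctl$tol,
                                    ctl$max_sweeps, ctl$brent_tol)
  lls <- fits$loglik
  lls[best] <- refined$loglik
  s1 <- aln$seqs["S1", ]
  s2 <- aln$seqs["S2", ]
  ok <- s1 %in% BASES & s2 %in% BASES
  structure(list(
    topology = best,
    parent = topo$parent, child = topo$child,
    lengths = as.numeric(refined$lengths),
    loglik = refined$loglik, all_loglik = lls,
    model = model,
    converged = isTRUE(refined$converged),
    s_divergence = if (any(ok)) mean(s1[ok] != s2[ok]) else NA_real_,
    n_columns = ncol(aln$seqs),
    pass_length = ncol(aln$seqs) >= ctl$min_columns,
    region = aln$region,
    supports = NULL
  ), class = "tree_result")
}

#' @export
print.tree_result <- function(x, ...) {
  cat("tree_result:", tree_newick(x), "\n")
  cat(sprintf("  topology %d, logL %.3f, %d columns%s\n", x$topology,
              x$loglik, x$n_columns,
              if (!is.null(x$supports))
                paste0(", min support ", min(x$supports)) else ""))
  invisible(x)
}

#' Newick string of a fitted tree
#'
#' @param tree A `tree_result`.
#' @param digits Branch-length digits.
#' @return Newick string (rooted at the node adjacent to OUT; internal-edge
#'   bootstrap supports, when present, are attached as node labels).
#' @export
tree_newick <- function(tree, digits = 6) {
  topo <- resolve_topology(tree$topology)
  len_of <- setNames(tree$lengths, paste(topo$parent, topo$child))
  rec <- function(node, par) {
    kids <- setdiff(topo$children_of[[node]], par)
    if (node <= 5L) return(TAXA[node])
    lab <- ""
    if (!is.null(tree$supports)) {
      e <- which(topo$child == node)
      if (length(e) == 1) {
        key <- topo$splits[match(node, topo$child[topo$child > 5L])]
        if (!is.na(key) && key %in% names(tree$supports))
          lab <- format(tree$supports[[key]])
      }
    }
    paste0("(", paste(vapply(kids, function(k)
      paste0(rec(k, node), ":",
             format(len_of[[paste(node, k)]], digits = digits)),
      ""), collapse = ","), ")", lab)
  }
  root_kids <- topo$children_of[[topo$root]]
  paste0("(", paste(vapply(root_kids, function(k)
    paste0(rec(k, topo$root), ":",
           format(len_of[[paste(topo$root, k)]], digits = digits)), ""),
    collapse = ","), ");")
}

#' Bootstrap support for the internal edges of the ML tree
#'
#' Resamples alignment columns with replacement, refits the ML topology per
#' replicate (model parameters held at the original fit, the standard
#' RAxML-style fast bootstrap), and reports for each internal edge of the
#' original ML tree the percentage of replicates whose ML topology contains
#' the same bipartition.
#'
#' @param aln A [assemble_alignment()] result.
#' @param tree A `tree_result` from [fit_ml_tree()] (fit fresh if `NULL`).
#' @param n_reps Number of replicates (default 100).
#' @param seed Integer seed; identical seeds give identical supports.
#' @param control Passed to the per-replicate fits (defaults to a faster
#'   tolerance than the original fit).
#' @return The `tree_result` with `supports` set: named percentages in
#'   `[0, 100]` per internal edge.
#' @export
bootstrap_support <- function(aln, tree = NULL, n_reps = 100, seed = 1,
                              control = list()) {
  stopifnot(n_reps >= 1)
  if (is.null(tree)) tree <- fit_ml_tree(aln, control = control)
  ctl <- modifyList(list(estimate_alpha = FALSE, tol = 1e-4, max_sweeps = 8,
                         brent_tol = 1e-3), control)
  topo <- resolve_topology(tree$topology)
  target <- topo$splits
  hits <- setNames(numeric(length(target)), target)
  nc <- ncol(aln$seqs)
  old_seed <- get_rng_state()
  on.exit(set_rng_state(old_seed))
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    rep_aln <- list(seqs = aln$seqs[, idx, drop = FALSE],
                    category = aln$category[idx], region = aln$region)
    rep_tree <- fit_ml_tree(rep_aln, model = tree$model, control = ctl)
    rep_splits <- resolve_topology(rep_tree$topology)$splits
    hits[target %in% rep_splits] <- hits[target %in% rep_splits] + 1
  }
  tree$supports <- 100 * hits / n_reps
  tree
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
set_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Filter fitted trees on bootstrap support and sexual divergence
#'
#' Keeps trees whose minimum internal-edge bootstrap support reaches
#' `min_support` and whose per-region S1-S2 pseudo-haplotype divergence is not
#' a high outlier (z-score across all supplied regions <= `z_max`); regions
#' with statistically elevated sexual heterozygosity typically correspond to
#' duplicated loci rather than single-copy sequence. Trees shorter than the
#' minimum column count recorded at fit time are also dropped.
#'
#' @param results list of `tree_result`s.
#' @param min_support Minimum internal-edge support in percent (default 70;
#'   0 disables, e.g. when no bootstrap was run).
#' @param z_max Maximum sexual-divergence z-score (default 3; `Inf` disables).
#' @return The passing subset, with an attribute `filter_log` giving counts
#'   per filter stage.
#' @export
filter_trees <- function(results, min_support = 70, z_max = 3) {
  stopifnot(length(results) > 0)
  sdiv <- vapply(results, `[[`, 0, "s_divergence")
  mu <- mean(sdiv, na.rm = TRUE)
  sdv <- sd(sdiv, na.rm = TRUE)
  z <- if (is.na(sdv) || sdv == 0) rep(0, length(sdiv)) else (sdiv - mu) / sdv
  min_sup <- vapply(results, function(r)
    if (is.null(r$supports)) if (min_support > 0) -Inf else Inf
    else min(r$supports), 0)
  pass_len <- vapply(results, function(r) isTRUE(r$pass_length), TRUE)
  keep <- min_sup >= min_support & z <= z_max & pass_len
  out <- results[keep]
  attr(out, "filter_log") <- c(
    n = length(results),
    fail_length = sum(!pass_len),
    fail_support = sum(min_sup < min_support),
    fail_divergence = sum(z > z_max),
    passing = sum(keep))
  out
}
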