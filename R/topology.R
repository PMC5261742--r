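TOPOLOGY_CLASSES <- c("H1", "H2", "P1", "C4", "B1", "B2")

node_tips <- function(topo, n)
  if (n <= 5L) n else topo$tipset[[which(topo$child == n)]]

#' Classify a five-taxon tree into the six topology classes
#'
#' With OUT as the root, the rooted four-tip ingroup shape is mapped (under
#' exchangeability of A1/A2 and of S1/S2) to one of six classes:
#' \describe{
#'   \item{H1 `(A,(A,(S,S)))`}{one apomict haplotype basal, the other sister
#'     to the sexual cherry: hybrid origin.}
#'   \item{H2 `(A,(S,(A,S)))`}{one apomict basal, the other nested among the
#'     sexual pseudo-haplotypes: hybrid origin.}
#'   \item{P1 `(S,(S,(A,A)))`}{a diverged apomict pair nested within basal
#'     sexual sequences: purely within-species origin.}
#'   \item{C4 `(S,(A,(A,S)))`, B1 `((A,A),(S,S))`, B2 `((A,S),(A,S))`}{
#'     ambiguous.}
#' }
#' The six classes partition all 15 labeled rooted topologies with
#' multiplicities H1:2, H2:4, P1:2, C4:4, B1:1, B2:2.
#'
#' @param tree A `tree_result` or a topology index 1..15.
#' @return list of class `topology_class` with `class` and `origin`
#'   (`"hybrid"`, `"pure"` or `"ambiguous"`).
#' @export
classify_topology <- function(tree) {
  topo <- resolve_topology(tree)
  kids <- setdiff(topo$children_of[[topo$root]], 5L)
  if (length(kids) != 2) stop("tree is not rooted by OUT")
  t1 <- node_tips(topo, kids[1])
  t2 <- node_tips(topo, kids[2])
  is_AA <- function(s) setequal(s, c(1L, 2L))
  is_SS <- function(s) setequal(s, c(3L, 4L))
  if (length(t1) == 2 && length(t2) == 2) {
    cls <- if (is_AA(t1) || is_SS(t1)) "B1" else "B2"
  } else {
    b <- if (length(t1) == 1) t1 else t2
    inner <- if (length(t1) == 1) kids[2] else kids[1]
    ik <- topo$children_of[[inner]]
    cherry <- node_tips(topo, ik[which.max(c(length(node_tips(topo, ik[1])),
                                             length(node_tips(topo, ik[2]))))])
    cls <- if (b %in% 1:2) {
      if (is_SS(cherry)) "H1" else "H2"
    } else {
      if (is_AA(cherry)) "P1" else "C4"
    }
  }
  origin <- switch(cls, H1 = , H2 = "hybrid", P1 = "pure", "ambiguous")
  structure(list(class = cls, origin = origin), class = "topology_class")
}

#' Summarize topology classes over a set of trees
#'
#' @param classes list of `tree_result`s (classified on the fly), list of
#'   [classify_topology()] results, or a character vector of class ids.
#' @return list with `table` (data.frame of counts and proportions per class)
#'   and `origin` (proportions of hybrid / pure / ambiguous calls).
#' @export
summarize_topologies <- function(classes) {
  if (is.list(classes))
    classes <- vapply(classes, function(x) {
      if (inherits(x, "topology_class")) x$class
      else if (inherits(x, "branch_mutations")) x$class$class
      else classify_topology(x)$class
    }, "")
  stopifnot(length(classes) >= 1, all(classes %in% TOPOLOGY_CLASSES))
  n <- table(factor(classes, levels = TOPOLOGY_CLASSES))
  tab <- data.frame(class = TOPOLOGY_CLASSES, count = as.integer(n),
                    proportion = as.numeric(n) / length(classes))
  origin <- c(hybrid = sum(tab$proportion[tab$class %in% c("H1", "H2")]),
              pure = tab$proportion[tab$class == "P1"],
              ambiguous = sum(tab$proportion[tab$class %in% c("C4", "B1", "B2")]))
  list(table = tab, origin = origin, n = length(classes))
}

#' Identify the conspecific-derived apomict haplotype
#'
#' In a hybrid tree, the apomict haplotype that most closely resembles the
#' sexual pseudo-haplotypes is the one inherited from the sexual species'
#' pedigree. Returns the apomict tip (A1 or A2) with the smaller mean
#' patristic distance to S1 and S2; an exact tie is flagged ambiguous (such a
#' tree is excluded from terminal contrasts).
#'
#' @param tree A `tree_result` with branch lengths.
#' @param strict Error on non-hybrid-class trees (default TRUE, the
#'   conservative setting for contrasts); `strict = FALSE` returns the
#'   closest apomict tip for any topology class.
#' @return list with `tip` (`"A1"`, `"A2"`, or `NA` on a tie) and `ambiguous`.
#' @export
identify_conspecific_tip <- function(tree, strict = TRUE) {
  stopifnot(inherits(tree, "tree_result"))
  cls <- classify_topology(tree)
  if (strict && cls$origin != "hybrid")
    stop("non-hybrid class input (", cls$class, "); use strict = FALSE to override")
  topo <- resolve_topology(tree)
  depth <- numeric(8)
  parent_of <- integer(8)
  # edges are postorder; reverse order guarantees parents before children
  for (e in rev(seq_along(topo$parent))) {
    depth[topo$child[e]] <- depth[topo$parent[e]] + tree$lengths[e]
    parent_of[topo$child[e]] <- topo$parent[e]
  }
  ancestors <- function(n) {
    out <- n
    while (n != topo$root) { n <- parent_of[n]; out <- c(out, n) }
    out
  }
  pat_dist <- function(i, j) {
    mrca_set <- intersect(ancestors(i), ancestors(j))
    depth[i] + depth[j] - 2 * max(depth[mrca_set][mrca_set > 5L | mrca_set == topo$root])
  }
  dA1 <- (pat_dist(1L, 3L) + pat_dist(1L, 4L)) / 2
  dA2 <- (pat_dist(2L, 3L) + pat_dist(2L, 4L)) / 2
  if (dA1 == dA2) return(list(tip = NA_character_, ambiguous = TRUE))
  list(tip = if (dA1 < dA2) "A1" else "A2", ambiguous = FALSE)
}

# ---- parsimony placement of derived mutations ----

.pars_cache <- new.env(parent = emptyenv())

# minimal-mutation edge set for one site pattern on a fixed rooted topology;
# returns integer edge indices, or NULL if the minimal placement is ambiguous
parsimony_edges <- function(topo, states) {
  key <- paste0(topo$id, ":", paste(states, collapse = ""))
  if (!is.null(.pars_cache[[key]])) {
    res <- .pars_cache[[key]]
    return(if (is.logical(res)) NULL else res)
  }
  grid <- .pars_cache[["grid"]]
  if (is.null(grid)) {
    grid <- as.matrix(expand.grid(1:4, 1:4, 1:4))  # states of nodes 6,7,8
    .pars_cache[["grid"]] <- grid
  }
  N <- cbind(matrix(states, 64, 5, byrow = TRUE), grid)
  ne <- length(topo$parent)
  diffs <- matrix(FALSE, 64, ne)
  for (e in seq_len(ne))
    diffs[, e] <- N[, topo$parent[e]] != N[, topo$child[e]]
  cost <- rowSums(diffs)
  minimal <- which(cost == min(cost))
  sets <- unique(apply(diffs[minimal, , drop = FALSE], 1, paste,
                       collapse = ""))
  res <- if (length(sets) == 1) which(diffs[minimal[1], ]) else TRUE
  .pars_cache[[key]] <- res
  if (is.logical(res)) NULL else res
}

#' Assign derived mutations to tree branches by parsimony
#'
#' For each variant alignment column, the derived state is any base differing
#' from the outgroup-rooted ancestral state; changes are placed on the fixed
#' tree by parsimony (enumerating internal-node states). Columns whose minimal
#' placement is not unique are discarded and counted; columns containing an
#' uncalled base are skipped. Tallies per branch are split into the five
#' annotation categories.
#'
#' @param tree A `tree_result`.
#' @param aln The [assemble_alignment()] used to fit it.
#' @return list of class `branch_mutations`: `counts` (branches x categories
#'   matrix; terminal branches named A1, A2, S1, S2, OUT, internal branches by
#'   their tip sets), `n_variant`, `n_placed`, `n_ambiguous`, `n_skipped`
#'   (placed + ambiguous + skipped = variant columns), plus the tree's
#'   `class` ([classify_topology()]) and `conspecific`
#'   ([identify_conspecific_tip()], non-strict).
#' @export
assign_branch_mutations <- function(tree, aln) {
  stopifnot(inherits(tree, "tree_result"))
  topo <- resolve_topology(tree)
  branch_names <- vapply(seq_along(topo$child), function(e) {
    ch <- topo$child[e]
    if (ch <= 5L) TAXA[ch] else paste(TAXA[topo$tipset[[e]]], collapse = "+")
  }, "")
  counts <- matrix(0L, length(branch_names), length(CATEGORIES),
                   dimnames = list(branch_names, CATEGORIES))
  st <- matrix(match(aln$seqs, BASES), nrow = 5)
  called <- colSums(!is.na(st)) == 5L
  cmax <- pmax(st[1, ], st[2, ], st[3, ], st[4, ], st[5, ], na.rm = TRUE)
  cmin <- pmin(st[1, ], st[2, ], st[3, ], st[4, ], st[5, ], na.rm = TRUE)
  differs <- !is.na(cmax) & cmax > cmin
  variant <- called & differs
  skipped <- sum(!called & differs)
  n_amb <- 0L
  for (j in which(variant)) {
    edges <- parsimony_edges(topo, st[, j])
    if (is.null(edges)) { n_amb <- n_amb + 1L; next }
    counts[edges, aln$category[j]] <- counts[edges, aln$category[j]] + 1L
  }
  structure(list(counts = counts,
                 n_variant = sum(variant) + skipped,
                 n_placed = sum(variant) - n_amb,
                 n_ambiguous = n_amb, n_skipped = skipped,
                 topology = tree$topology,
                 class = classify_topology(tree),
                 conspecific = identify_conspecific_tip(tree, strict = FALSE),
                 region = tree$region),
            class = "branch_mutations")
}

#' Terminal-branch contrasts of constrained versus neutral mutations
#'
#' Compares the mutation spectrum of the conspecific-derived apomict terminal
#' branch with the sexual terminal branches across trees. For H1-class trees
#' (sexual cherry) three 2x2 Fisher contrasts are formed: conspecific apomict
#' tip versus S1 (C1), versus S2 (C2) and versus the pooled sexual tips (C3);
#' for H2-class trees a single pooled contrast (C4). Cells are constrained
#' versus 4-fold derived-mutation counts summed over trees; the combined test
#' pools the cells of all contrasts.
#'
#' @param tables list of [assign_branch_mutations()] results (trees of
#'   non-hybrid class, or with an ambiguous conspecific tip, are skipped).
#' @param constrained Constrained category or categories (pooled).
#' @return data.frame of class `terminal_contrasts`: one row per contrast
#'   C1..C4 plus `combined`, with cells, odds ratio, log-odds SE and exact
#'   two-sided Fisher P (`NA` odds ratio on an empty cell; P still computed).
#' @export
terminal_contrasts <- function(tables, constrained = "0fold") {
  stopifnot(length(tables) >= 1,
            all(constrained %in% CONSTRAINED_CATEGORIES))
  cells <- matrix(0, 5, 4, dimnames = list(
    c("C1", "C2", "C3", "C4", "combined"),
    c("apo_constrained", "apo_neutral", "sex_constrained", "sex_neutral")))
  n_trees <- setNames(integer(5), rownames(cells))
  used <- 0L
  for (x in tables) {
    if (!inherits(x, "branch_mutations")) stop("need branch_mutations objects")
    if (x$class$origin != "hybrid" || is.na(x$conspecific$tip)) next
    used <- used + 1L
    apo <- c(sum(x$counts[x$conspecific$tip, constrained]),
             x$counts[x$conspecific$tip, "4fold"])
    s1 <- c(sum(x$counts["S1", constrained]), x$counts["S1", "4fold"])
    s2 <- c(sum(x$counts["S2", constrained]), x$counts["S2", "4fold"])
    add <- function(row, sex) {
      cells[row, ] <<- cells[row, ] + c(apo, sex)
      n_trees[row] <<- n_trees[row] + 1L
    }
    if (x$class$class == "H1") {
      add("C1", s1); add("C2", s2); add("C3", s1 + s2)
    } else add("C4", s1 + s2)
  }
  if (used == 0L) stop("no usable hybrid-class trees")
  cells["combined", ] <- colSums(cells[c("C1", "C2", "C3", "C4"), ])
  n_trees["combined"] <- sum(n_trees[c("C1", "C2", "C3", "C4")])
  out <- do.call(rbind, lapply(rownames(cells), function(rn) {
    cc <- cells[rn, ]
    tab <- matrix(cc, 2, 2, byrow = TRUE)
    if (sum(cc) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      ft <- list(odds_ratio = NA_real_, p_value = NA_real_, se = NA_real_)
    } else ft <- fisher_pair_test(tab)
    data.frame(contrast = rn, n_trees = n_trees[rn],
               apo_constrained = cc[1], apo_neutral = cc[2],
               sex_constrained = cc[3], sex_neutral = cc[4],
               odds_ratio = ft$odds_ratio, se = ft$se, p_value = ft$p_value,
               row.names = NULL)
  }))
  class(out) <- c("terminal_contrasts", "data.frame")
  out
}

#' Terminal-branch mutation ratio and binomial test against the 2x null
#'
#' Because sexual pseudo-haplotypes split heterozygous mutations between two
#' tips (and homozygous mutations fall on their shared stem), equal mutation
#' accumulation predicts apomict terminal branches *at most* twice as long as
#' the summed sexual tips. The conservative null is therefore a 2x excess:
#' an exact one-sided binomial test of the apomict terminal count out of
#' (apomict + summed sexual counts) against p0 = 2/3.
#'
#' @param tables list of [assign_branch_mutations()] results; trees with an
#'   ambiguous conspecific tip are skipped (all topology classes are used).
#' @return list: `ratio` (apomict / summed sexual terminal mutations; 2.0
#'   under the null), `ratio_per_tip` (apomict / mean per-sexual-tip),
#'   `n_apomict`, `n_sexual`, `n_trees`, one-sided upper-tail `p_value`.
#' @export
branch_length_ratio_test <- function(tables) {
  stopifnot(length(tables) >= 1)
  apo <- sex <- 0
  n_used <- 0L
  for (x in tables) {
    if (is.na(x$conspecific$tip)) next
    n_used <- n_used + 1L
    apo <- apo + sum(x$counts[x$conspecific$tip, ])
    sex <- sex + sum(x$counts[c("S1", "S2"), ])
  }
  if (apo + sex == 0)
    return(list(ratio = NA_real_, ratio_per_tip = NA_real_, n_apomict = 0,
                n_sexual = 0, n_trees = n_used, p_value = NA_real_))
  list(ratio = if (sex > 0) apo / sex else NA_real_,
       ratio_per_tip = if (sex > 0) apo / (sex / 2) else NA_real_,
       n_apomict = apo, n_sexual = sex, n_trees = n_used,
       p_value = pbinom(apo - 1, apo + sex, 2 / 3, lower.tail = FALSE))
}
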