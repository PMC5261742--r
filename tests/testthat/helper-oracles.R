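# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's computational paths: likelihoods by brute-force state enumeration
# with Matrix::expm, exact tests by direct hypergeometric/binomial summation,
# diversity statistics by per-site loops.

FAST_CTL <- list(estimate_alpha = FALSE, k = 1, init_alpha = Inf)

rdirichlet1 <- function(k) { x <- rgamma(k, 2); x / sum(x) }

CATS <- annotation_categories()
n_sites <- apomacc:::n_sites

# small genotype table with a uniform annotation ("other" everywhere unless
# intervals given); reference defaults to the REF alleles placed on a random
# background
tiny_fixture <- function(geno, pos = seq_len(nrow(geno)) * 3L, ref = NULL,
                         alt = NULL, qual = 100, chrom = "chr1",
                         chrom_len = max(pos) + 10L, intervals = NULL,
                         seed = 99) {
  set.seed(seed)
  g <- as.matrix(geno)
  n <- nrow(g)
  if (is.null(colnames(g)))
    colnames(g) <- paste0("s", seq_len(ncol(g)))
  if (is.null(ref)) ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (is.null(alt)) alt <- chartr("ACGT", "CAGT", ref)  # A<->C, G->G? no:
  # ensure alt differs from ref
  alt[alt == ref] <- chartr("ACGT", "GTAC", ref[alt == ref])
  seq_chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  seq_chars[pos] <- ref
  reference <- setNames(paste(seq_chars, collapse = ""), chrom)
  if (is.null(intervals))
    intervals <- data.frame(chrom = chrom, start = 0L, end = chrom_len,
                            category = "other")
  ann <- site_annotation(intervals, reference)
  tab <- genotype_table(
    data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
               qual = rep_len(qual, n), stringsAsFactors = FALSE),
    g, chrom_lengths = setNames(chrom_len, chrom))
  list(table = tab, ann = ann, reference = reference)
}

# exhaustive-state pruning oracle: P(t) via matrix exponentials, likelihood by
# summation over all 4^3 internal-node state assignments per rate category
bf_loglik <- function(aln, topology, lengths, model) {
  topo <- apomacc:::resolve_topology(topology)
  bases <- c("A", "C", "G", "T")
  states <- matrix(match(aln$seqs, bases), nrow = 5)
  grid <- as.matrix(expand.grid(s6 = 1:4, s7 = 1:4, s8 = 1:4))
  ll <- 0
  for (col in seq_len(ncol(states))) {
    col_lik <- 0
    for (r in model$rates) {
      P <- lapply(lengths * r, function(t)
        as.matrix(Matrix::expm(model$Q * t)))
      lik <- 0
      for (gi in seq_len(nrow(grid))) {
        full <- c(states[, col], grid[gi, ])
        term <- model$pi[full[topo$root]]
        for (e in seq_along(topo$parent)) {
          sp <- full[topo$parent[e]]
          sc <- full[topo$child[e]]
          term <- term * if (is.na(sc)) 1 else P[[e]][sp, sc]
        }
        # missing tip states: P rows sum to 1, handled by the NA branch above;
        # missing internal states cannot occur (grid enumerates all)
        if (anyNA(full[topo$parent])) stop("internal NA")
        lik <- lik + term
      }
      col_lik <- col_lik + lik / length(model$rates)
    }
    ll <- ll + log(col_lik)
  }
  ll
}

# two-sided Fisher P by direct hypergeometric enumeration
bf_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# one-sided upper-tail binomial P by direct summation
bf_binom_upper <- function(x, n, p) {
  if (x > n) return(0)
  sum(vapply(x:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

# per-site tally oracle for H0 / D of one sample
bf_diversity <- function(table, ann, sample, category = NULL) {
  g <- table$geno[, sample]
  n_het <- n_homalt <- n_poly <- 0
  cats <- ann_category(ann, table$sites$chrom, table$sites$pos)
  for (i in seq_along(g)) {
    if (!is.null(category) && cats[i] != category) next
    if (is.na(g[i])) next
    n_poly <- n_poly + 1
    if (g[i] == 1) n_het <- n_het + 1
    if (g[i] == 2) n_homalt <- n_homalt + 1
  }
  list(n_het = n_het, n_homalt = n_homalt, n_poly = n_poly,
       H0 = n_het / n_poly)
}

# exhaustive minimum spanning tree for 3 nodes
bf_mst3 <- function(d) {
  trees <- list(c(1, 2, 1, 3), c(1, 2, 2, 3), c(1, 3, 2, 3))
  w <- vapply(trees, function(t) d[t[1], t[2]] + d[t[3], t[4]], 0)
  list(weight = min(w), edges = trees[[which.min(w)]])
}

# simulate a 5-taxon alignment directly on a given topology under the model
# (independent of the cohort simulator); returns a tax5_alignment-like list
sim_alignment_on_tree <- function(topology, lengths, model, n_col, seed) {
  set.seed(seed)
  topo <- apomacc:::resolve_topology(topology)
  bases <- c("A", "C", "G", "T")
  P <- lapply(lengths, function(t) as.matrix(Matrix::expm(model$Q * t)))
  seqs <- matrix(NA_integer_, 8, n_col)
  seqs[topo$root, ] <- sample.int(4, n_col, replace = TRUE, prob = model$pi)
  for (e in rev(seq_along(topo$parent))) {   # parents before children
    par_states <- seqs[topo$parent[e], ]
    seqs[topo$child[e], ] <- vapply(par_states, function(s)
      sample.int(4, 1, prob = P[[e]][s, ]), 0L)
  }
  m <- matrix(bases[seqs[1:5, ]], nrow = 5,
              dimnames = list(c("A1", "A2", "S1", "S2", "OUT"), NULL))
  list(seqs = m, pos = seq_len(n_col),
       category = rep("other", n_col),
       region = list(chrom = "chr1", start = 0L, end = n_col))
}

# full small-cohort analysis used by the calibration/power criteria:
# runs the package path end to end (simulate -> filter -> polarize ->
# pooled ratio Z test; optionally trees -> contrasts + binomial ratio test)
cohort_stats <- function(seed, rho, selfing_F = 0.75, genome_length = 1e6,
                         n_blocks = 12, block_bp = 2000, do_trees = TRUE,
                         constrained = "0fold") {
  p <- sim_params(genome_length = genome_length, relax_factor_rho = rho,
                  selfing_F = selfing_F, n_blocks = n_blocks,
                  block_bp = block_bp, seed = seed)
  co <- simulate_cohort(p)
  tb <- suppressWarnings(filter_sites(co$table, min_callable_frac = 0))
  tb <- polarize_derived(tb, co$ann)
  cs <- ann_category(co$ann, tb$sites$chrom, tb$sites$pos)
  cb <- category_bases(co$ann, tb$windows)
  # the ratio statistic is per sample; the Z test contrasts one sympatric
  # pair (pooling across samples would pseudo-replicate mutations shared
  # through the hybrid origins and the species trunk, inflating the variance
  # beyond the naive log-odds SE)
  apo <- diversity_summary(tb, co$ann, co$samples$apomict[1], cs, cb)
  sex <- diversity_summary(tb, co$ann, co$samples$sexual[1], cs, cb)
  zt <- odds_ratio_z_test(constrained_neutral_ratio(apo, constrained),
                          constrained_neutral_ratio(sex, constrained))
  out <- list(z = zt$z, z_p = zt$p_value)
  if (!do_trees) return(out)
  tabs <- vector("list", nrow(co$blocks))
  for (i in seq_len(nrow(co$blocks))) {
    blk <- co$blocks[i, ]
    sx <- co$samples$sexual[match(blk$sample, co$samples$apomict)]
    ps <- make_pseudo_haplotypes(tb, co$reference, sx,
                                 list(chrom = blk$chrom, start = blk$start,
                                      end = blk$end), seed = seed + i)
    aln <- assemble_alignment(blk, ps, co$reference, co$ann)
    tr <- fit_ml_tree(aln, control = FAST_CTL)
    tabs[[i]] <- assign_branch_mutations(tr, aln)
  }
  tc <- terminal_contrasts(tabs, constrained = constrained)
  comb <- tc[tc$contrast == "combined", ]
  bt <- branch_length_ratio_test(tabs)
  c(out, list(combined_or = comb$odds_ratio, combined_p = comb$p_value,
              binom_p = bt$p_value, ratio = bt$ratio, tabs = length(tabs)))
}
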