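fake_tree <- function(id, lengths = rep(0.1, 7)) {
  topo <- topologies5()[[id]]
  structure(list(topology = id, parent = topo$parent, child = topo$child,
                 lengths = lengths, loglik = 0, model = NULL,
                 region = list(chrom = "chr1", start = 0L, end = 100L)),
            class = "tree_result")
}

basal_tip <- function(id) {
  topo <- topologies5()[[id]]
  kids <- setdiff(topo$children_of[[topo$root]], 5L)
  sizes <- vapply(kids, function(k) length(apomacc:::node_tips(topo, k)), 0L)
  if (all(sizes == 2)) NA_integer_ else kids[sizes == 1]
}

test_that("the six classes partition the 15 rooted topologies", {
  cls <- vapply(1:15, function(i) classify_topology(i)$class, "")
  expect_equal(as.list(table(cls)),
               list(B1 = 1L, B2 = 2L, C4 = 4L, H1 = 2L, H2 = 4L, P1 = 2L))
  origins <- vapply(1:15, function(i) classify_topology(i)$origin, "")
  expect_equal(sum(origins == "hybrid"), 6L)   # 6/15 hybrid
  expect_equal(sum(origins == "pure"), 2L)
})

test_that("named example topologies classify as stated", {
  # (OUT,(A1,(A2,(S1,S2)))): A1 basal, A2 sister to the sexual cherry
  h1_ids <- which(vapply(1:15, function(i)
    classify_topology(i)$class == "H1", TRUE))
  expect_equal(sort(vapply(h1_ids, basal_tip, 0L)), c(1L, 2L))
  expect_equal(classify_topology(h1_ids[1])$origin, "hybrid")
  # (OUT,(S1,(S2,(A1,A2)))): sexuals basal, diverged apomict pair nested
  p1_ids <- which(vapply(1:15, function(i)
    classify_topology(i)$class == "P1", TRUE))
  expect_equal(sort(vapply(p1_ids, basal_tip, 0L)), c(3L, 4L))
  expect_equal(classify_topology(p1_ids[1])$origin, "pure")
})

test_that("classification is invariant under within-role label swaps", {
  swap_splits <- function(topo, map) {
    vapply(topo$splits, function(s) {
      tips <- sort(map[as.integer(strsplit(s, ",")[[1]])])
      paste(tips, collapse = ",")
    }, "")
  }
  tset <- topologies5()
  sig <- vapply(tset, function(t) paste(sort(t$splits), collapse = "|"), "")
  for (map in list(c(2L, 1L, 3L, 4L, 5L), c(1L, 2L, 4L, 3L, 5L))) {
    for (i in 1:15) {
      sw <- paste(sort(swap_splits(tset[[i]], map)), collapse = "|")
      j <- match(sw, sig)
      expect_equal(classify_topology(i)$class, classify_topology(j)$class)
    }
  }
})

test_that("conspecific tip identification follows patristic distance", {
  h1_ids <- which(vapply(1:15, function(i)
    classify_topology(i)$class == "H1", TRUE))
  # basal A1: A2 sits inside the sexual clade and must be returned
  id <- h1_ids[vapply(h1_ids, basal_tip, 0L) == 1L]
  expect_equal(identify_conspecific_tip(fake_tree(id))$tip, "A2")
  id2 <- h1_ids[vapply(h1_ids, basal_tip, 0L) == 2L]
  expect_equal(identify_conspecific_tip(fake_tree(id2))$tip, "A1")
  # an exact tie is ambiguous: B1 with symmetric lengths
  b1 <- which(vapply(1:15, function(i)
    classify_topology(i)$class == "B1", TRUE))[1]
  tie <- identify_conspecific_tip(fake_tree(b1), strict = FALSE)
  expect_true(tie$ambiguous)
  expect_true(is.na(tie$tip))
  # strict mode rejects non-hybrid classes
  expect_error(identify_conspecific_tip(fake_tree(b1)), "non-hybrid")
})

mk_aln_topo <- function(cols, cats = "other") {
  m <- do.call(cbind, lapply(cols, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- c("A1", "A2", "S1", "S2", "OUT")
  list(seqs = m, pos = seq_len(ncol(m)),
       category = rep_len(cats, ncol(m)),
       region = list(chrom = "chr1", start = 0L, end = ncol(m)))
}

test_that("parsimony places single- and shared-tip mutations correctly", {
  # use an H1 topology with S1,S2 as a cherry
  h1 <- which(vapply(1:15, function(i)
    classify_topology(i)$class == "H1", TRUE))[1]
  tr <- fake_tree(h1)
  #          A1A2S1S2OUT: col1 S1 private; col2 S1+S2 shared; col3 invariant
  aln <- mk_aln_topo(c("AATAA", "AATTA", "AAAAA", "GAAAA"),
                     cats = c("0fold", "4fold", "other", "CNS"))
  bm <- assign_branch_mutations(tr, aln)
  expect_equal(unname(bm$counts["S1", "0fold"]), 1L)
  expect_equal(sum(bm$counts[, "0fold"]), 1L)
  expect_equal(unname(bm$counts["S1+S2", "4fold"]), 1L)  # cherry stem
  expect_equal(unname(bm$counts["S1", "4fold"] + bm$counts["S2", "4fold"]), 0L)
  expect_equal(unname(bm$counts["A1", "CNS"]), 1L)
  # conservation: placed + ambiguous + skipped = variant columns
  expect_equal(bm$n_placed + bm$n_ambiguous + bm$n_skipped, bm$n_variant)
  expect_equal(bm$n_variant, 3L)
})

test_that("terminal contrast cells and tests behave per contract", {
  mk_bm <- function(class, tip, apo, s1, s2) {
    counts <- matrix(0L, 7, 5,
                     dimnames = list(c("A1", "A2", "S1", "S2", "OUT",
                                       "x", "y"), CATS))
    counts["A1", ] <- 0L
    counts[tip, c("0fold", "4fold")] <- apo
    counts["S1", c("0fold", "4fold")] <- s1
    counts["S2", c("0fold", "4fold")] <- s2
    structure(list(counts = counts,
                   class = list(class = class,
                                origin = if (class %in% c("H1", "H2"))
                                  "hybrid" else "ambiguous"),
                   conspecific = list(tip = tip, ambiguous = FALSE)),
              class = "branch_mutations")
  }
  # identical apomict and sexual count vectors: all ORs 1, P 1
  tc <- terminal_contrasts(list(mk_bm("H1", "A1", c(10L, 20L), c(10L, 20L),
                                      c(10L, 20L))))
  expect_equal(tc$odds_ratio[!is.na(tc$odds_ratio)],
               rep(1, sum(!is.na(tc$odds_ratio))))
  expect_equal(tc$p_value[!is.na(tc$p_value)],
               rep(1, sum(!is.na(tc$p_value))))
  # combined cells are the column sums of the per-contrast cells
  tabs <- list(mk_bm("H1", "A1", c(9L, 3L), c(2L, 5L), c(1L, 4L)),
               mk_bm("H2", "A2", c(7L, 2L), c(3L, 3L), c(2L, 2L)))
  tc2 <- terminal_contrasts(tabs)
  cellcols <- c("apo_constrained", "apo_neutral", "sex_constrained",
                "sex_neutral")
  expect_equal(unlist(tc2[tc2$contrast == "combined", cellcols]),
               colSums(as.matrix(tc2[tc2$contrast != "combined", cellcols])),
               ignore_attr = TRUE)
  # H1 trees feed C1-C3, H2 trees C4; ambiguous-tip trees are skipped
  expect_equal(tc2$n_trees, c(1L, 1L, 1L, 1L, 4L), ignore_attr = TRUE)
  expect_error(terminal_contrasts(list(mk_bm("B1", "A1", c(1L, 1L),
                                             c(1L, 1L), c(1L, 1L)))),
               "no usable hybrid")
})

test_that("branch-length ratio test matches its stated null and oracle", {
  mk_bm2 <- function(apo, s1, s2) {
    counts <- matrix(0L, 5, 5,
                     dimnames = list(c("A1", "A2", "S1", "S2", "OUT"), CATS))
    counts["A1", "other"] <- apo
    counts["S1", "other"] <- s1
    counts["S2", "other"] <- s2
    structure(list(counts = counts,
                   class = list(class = "H1", origin = "hybrid"),
                   conspecific = list(tip = "A1", ambiguous = FALSE)),
              class = "branch_mutations")
  }
  bt <- branch_length_ratio_test(list(mk_bm2(200L, 50L, 50L)))
  expect_equal(bt$ratio, 2)
  expect_equal(bt$ratio_per_tip, 4)
  expect_lt(abs(bt$p_value - 0.5), 0.06)   # the null holds exactly
  bt2 <- branch_length_ratio_test(list(mk_bm2(20L, 5L, 5L)))
  expect_equal(bt2$p_value, bf_binom_upper(20, 30, 2 / 3), tolerance = 1e-12)
  expect_true(is.na(branch_length_ratio_test(list(mk_bm2(0L, 0L, 0L)))$ratio))
})

test_that("terminal counts track the truth log across simulated regions", {
  co <- simulate_cohort(sim_params(genome_length = 2e5, seed = 23,
                                   n_blocks = 3, block_bp = 2000))
  tb <- polarize_derived(
    suppressWarnings(filter_sites(co$table, min_callable_frac = 0)), co$ann)
  mu <- co$truth$mutations; ca <- co$truth$carriers
  tree_tot <- truth_tot <- 0
  for (i in seq_len(nrow(co$blocks))) {
    blk <- co$blocks[i, ]
    sx <- co$samples$sexual[match(blk$sample, co$samples$apomict)]
    ps <- make_pseudo_haplotypes(tb, co$reference, sx,
                                 list(chrom = blk$chrom, start = blk$start,
                                      end = blk$end), seed = i)
    aln <- assemble_alignment(blk, ps, co$reference, co$ann)
    tr <- fit_ml_tree(aln, control = FAST_CTL)
    bm <- assign_branch_mutations(tr, aln)
    if (is.na(bm$conspecific$tip)) next
    tree_tot <- tree_tot + sum(bm$counts[bm$conspecific$tip, ])
    sel <- ca$sample == blk$sample & ca$hap == 1L &
      mu$pos[ca$mut] > blk$start & mu$pos[ca$mut] <= blk$end &
      mu$class[ca$mut] %in% c("origin_stem", "apo_private", "apo_shared")
    truth_tot <- truth_tot + sum(sel)
  }
  expect_lt(abs(tree_tot - truth_tot), 0.05 * truth_tot + 1)
})

test_that("topology summaries are proportions that sum to one", {
  s <- summarize_topologies(c("H1", "H1", "H2", "P1", "B1"))
  expect_equal(sum(s$table$proportion), 1)
  expect_equal(sum(s$table$count), 5L)
  expect_equal(unname(s$origin[["hybrid"]]), 0.6)
  s2 <- summarize_topologies(rep("H1", 4))
  expect_equal(unname(s2$origin[["hybrid"]]), 1)
  expect_error(summarize_topologies(character(0)))
})
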