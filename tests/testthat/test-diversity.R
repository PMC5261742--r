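test_that("H0 and D follow their definitions on a crafted sample", {
  # 10 polymorphic called sites, 4 het; genome of 100 "other" bases so the
  # D denominator is 100: D = (0.5*2 + 3)/100 with 2 het + 3 homalt called
  g <- cbind(a = c(rep(1L, 4), rep(0L, 4), 2L, 2L),
             b = c(rep(0L, 4), rep(1L, 4), 0L, 1L))
  fx <- tiny_fixture(g, pos = seq(2, 92, by = 10), chrom_len = 100L)
  ds <- diversity_summary(fx$table, fx$ann, "a")
  all_row <- ds[ds$category == "all", ]
  expect_equal(all_row$n_polymorphic, 10)
  expect_equal(all_row$H0, 0.4)
  g2 <- cbind(a = c(rep(1L, 2), rep(2L, 3), rep(0L, 5)),
              b = c(rep(0L, 5), rep(1L, 5)))
  fx2 <- tiny_fixture(g2, pos = seq(2, 92, by = 10), chrom_len = 100L)
  d2 <- diversity_summary(fx2$table, fx2$ann, "a")
  expect_equal(d2[d2$category == "all", "D"], (0.5 * 2 + 3) / 100)
})

test_that("summaries match a per-site tally oracle on a random fixture", {
  set.seed(7)
  g <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, NA), 200 * 3, replace = TRUE), 200)
  colnames(g) <- c("x", "y", "z")
  keep <- apomacc:::is_polymorphic(g)
  g <- g[keep, , drop = FALSE]
  iv <- data.frame(chrom = "chr1",
                   start = c(0L, 300L, 600L),
                   end = c(300L, 600L, 1000L),
                   category = c("0fold", "4fold", "other"))
  fx <- tiny_fixture(g, pos = sort(sample(1:1000, nrow(g))),
                     chrom_len = 1000L, intervals = iv)
  for (s in c("x", "y", "z")) {
    ds <- diversity_summary(fx$table, fx$ann, s)
    for (cc in c("0fold", "4fold", NULL)) {
      oracle <- bf_diversity(fx$table, fx$ann, s, cc)
      row <- ds[ds$category == cc, ]
      expect_equal(row$n_het, oracle$n_het)
      expect_equal(row$n_homalt, oracle$n_homalt)
      expect_equal(row$n_polymorphic, oracle$n_poly)
      if (oracle$n_poly > 0) expect_equal(row$H0, oracle$H0)
    }
  }
})

test_that("D over all sites is the callable-weighted mean of category D", {
  co <- simulate_cohort(sim_params(genome_length = 2e5, seed = 21))
  tb <- polarize_derived(
    suppressWarnings(filter_sites(co$table, min_callable_frac = 0)), co$ann)
  ds <- diversity_summary(tb, co$ann, "apo_pop1")
  cats <- ds[ds$category != "all", ]
  expect_equal(ds$D[ds$category == "all"],
               sum(cats$D * cats$n_sites_called) / sum(cats$n_sites_called))
  expect_equal(sum(cats$n_polymorphic), ds$n_polymorphic[ds$category == "all"])
})

test_that("constrained/neutral ratio arithmetic and undefined markers", {
  mk <- function(d0, d4, n = 1000) {
    su <- data.frame(sample = "s", category = c("0fold", "4fold"),
                     n_sites_called = n, n_polymorphic = n,
                     n_het = 0, n_homalt = 0,
                     n_derived = c(d0, d4) * 2 * n)
    class(su) <- c("diversity_summary", "data.frame")
    su
  }
  rs <- constrained_neutral_ratio(mk(0.02, 0.04), "0fold")
  expect_equal(rs$ratio, 0.5)
  expect_equal(unname(rs$cells["a"]), 0.02 * 2000)
  # D(4fold) = 0 yields an undefined marker, not an error
  expect_true(is.na(constrained_neutral_ratio(mk(0.02, 0), "0fold")$ratio))
  expect_true(is.na(constrained_neutral_ratio(mk(0, 0.04), "0fold")$se))
})

test_that("fisher_pair_test: arithmetic, symmetry and enumeration oracle", {
  sym <- fisher_pair_test(rbind(c(10, 90), c(10, 90)))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  ft <- fisher_pair_test(rbind(c(10, 90), c(20, 80)))
  expect_equal(ft$odds_ratio, (10 * 80) / (90 * 20))
  expect_equal(ft$p_value, bf_fisher_p(rbind(c(10, 90), c(20, 80))))
  expect_error(fisher_pair_test(rbind(c(1.5, 2), c(3, 4))), "integers")
  expect_error(fisher_pair_test(rbind(c(-1, 2), c(3, 4))), "integers")
  # P invariant under row and column swaps
  set.seed(3)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 15), 2)
    p <- fisher_pair_test(tab)$p_value
    expect_equal(fisher_pair_test(tab[2:1, ])$p_value, p)
    expect_equal(fisher_pair_test(tab[, 2:1])$p_value, p)
    expect_equal(fisher_pair_test(tab)$p_value, bf_fisher_p(tab))
  }
})

test_that("odds-ratio Z test: convention, antisymmetry, undefined cells", {
  s <- function(lo, se) list(log_odds = lo, se = se)
  same <- odds_ratio_z_test(s(0.5, 0.1), s(0.5, 0.1))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 0.5)
  a <- s(1, 0.3); b <- s(0.2, 0.4)
  expect_equal(odds_ratio_z_test(a, b)$z, -odds_ratio_z_test(b, a)$z)
  expect_true(is.na(odds_ratio_z_test(s(1, NA), b)$p_value))
  # the one-sided upper-tail convention reproduces the printed (Z, P) pairs
  expect_lt(abs(pnorm(1.56, lower.tail = FALSE) - 0.059), 5e-4)
  expect_lt(abs(pnorm(2.7, lower.tail = FALSE) - 0.003), 5e-4)
})

test_that("window profiles: degenerate cases and hand-computed tally", {
  g_same <- cbind(s1 = rep(c(0L, 1L, 2L), 10), s2 = rep(c(0L, 1L, 2L), 10),
                  apo = rep(1L, 30))
  fx <- tiny_fixture(g_same, pos = 1:30 * 5, chrom_len = 200L)
  w <- window_profiles(fx$table, fx$ann, c("s1", "s2"), "apo",
                       window_snps = 10)
  expect_equal(nrow(w), 3)
  expect_equal(w$sexual_dij, rep(0, 3))        # identical sexual genotypes
  expect_equal(w$apomict_H0, rep(1, 3))
  expect_equal(w$n_snps, rep(10L, 3))
  g_opp <- cbind(s1 = rep(0L, 25), s2 = rep(2L, 25), apo = rep(0L, 25))
  fx2 <- tiny_fixture(g_opp, pos = 1:25 * 5, chrom_len = 200L)
  w2 <- window_profiles(fx2$table, fx2$ann, c("s1", "s2"), "apo",
                        window_snps = 10)
  expect_equal(w2$sexual_dij, rep(1, 3))       # opposite homozygotes
  expect_equal(w2$n_snps, c(10L, 10L, 5L))     # trailing partial window
  # 50-SNP window against a brute-force pairwise tally over three sexuals
  set.seed(15)
  g <- matrix(sample(c(0:2, NA), 50 * 4, replace = TRUE,
                     prob = c(.4, .3, .2, .1)), 50)
  colnames(g) <- c("a", "b", "c", "apo")
  keep <- apomacc:::is_polymorphic(g)
  fx3 <- tiny_fixture(g[keep, ], pos = which(keep) * 7, chrom_len = 400L)
  w3 <- window_profiles(fx3$table, fx3$ann, c("a", "b", "c"), "apo",
                        window_snps = 100)
  pairs <- combn(c("a", "b", "c"), 2)
  per_pair <- apply(pairs, 2, function(pr) {
    gi <- fx3$table$geno[, pr[1]]; gj <- fx3$table$geno[, pr[2]]
    mean(abs(gi - gj)[!is.na(gi) & !is.na(gj)] / 2)
  })
  expect_equal(w3$sexual_dij, mean(per_pair), tolerance = 1e-12)
  expect_error(window_profiles(fx3$table, fx3$ann, "a", "apo"), "2")
})

test_that("derived-frequency bins partition the apomict-derived sites", {
  co <- simulate_cohort(sim_params(genome_length = 2e5, seed = 31))
  tb <- polarize_derived(
    suppressWarnings(filter_sites(co$table, min_callable_frac = 0)), co$ann)
  apos <- co$samples$apomict[1:7]
  fb <- freq_binned_ratios(tb, co$ann, apos, co$samples$sexual)
  dd <- apomacc:::derived_dose(tb)[, apos]
  nbin <- rowSums(dd > 0, na.rm = TRUE)
  expect_equal(fb$n_sites, as.numeric(table(factor(nbin, levels = 1:7))))
  expect_equal(sum(fb$n_sites), sum(nbin > 0))
  # site where all 7 apomicts are het for the derived allele -> top bin
  g <- cbind(matrix(1L, 2, 7, dimnames = list(NULL, paste0("apo", 1:7))),
             sex1 = c(0L, 1L))
  fx <- tiny_fixture(g, pos = c(10L, 20L), chrom_len = 50L)
  fb2 <- freq_binned_ratios(fx$table, fx$ann, paste0("apo", 1:7), "sex1")
  expect_equal(fb2$n_sites, c(rep(0, 6), 2))
})

test_that("frequency bins separate founder divergence from new mutations", {
  # under relaxed retention (rho = 3), sites shared by all apomicts of an
  # origin are founder divergence (sexual-retention spectrum: apomict/sexual
  # ratio difference near zero), while intermediate bins hold post-origin
  # clone-genealogy mutations carrying the planted excess
  co <- simulate_cohort(sim_params(genome_length = 4e5, relax_factor_rho = 3,
                                   seed = 41))
  tb <- polarize_derived(
    suppressWarnings(filter_sites(co$table, min_callable_frac = 0)), co$ann)
  shared <- co$samples$apomict[1:7]   # the shared-origin cluster
  fb <- freq_binned_ratios(tb, co$ann, shared, co$samples$sexual,
                           constrained = c("0fold", "CNS", "CCS"))
  # truth: founder-divergence and species-stem sites sit in the top bin
  mu <- co$truth$mutations
  founder_pos <- mu$pos[mu$class %in% c("founder_divergence", "species_trunk") &
                          (is.na(mu$origin) | mu$origin == 1)]
  dd <- apomacc:::derived_dose(tb)[, shared]
  bin <- rowSums(dd > 0, na.rm = TRUE)
  founder_bins <- bin[tb$sites$pos %in% founder_pos]
  expect_gte(mean(founder_bins == 7), 0.99)
  # founder bin: no apomict excess (sexual-retention spectrum on both sides)
  expect_lt(abs(fb$z[7]), 2)
  # intermediate bins: the apomict-side constrained/neutral enrichment is
  # elevated relative to the founder bin (the sexual comparator is degenerate
  # there: independent sexual lineages carry no derived alleles at
  # apomict-private sites, so z is an undefined marker)
  mid <- fb$ratio_apo[3:6]
  expect_gt(mean(mid[is.finite(mid)]), fb$ratio_apo[7] * 1.5)
})

test_that("distance network: metric properties and exhaustive MST", {
  g <- cbind(u = c(0L, 1L, 2L, 0L), v = c(0L, 1L, 2L, 0L),
             w = c(2L, 1L, 0L, 2L))
  fx <- tiny_fixture(g, pos = c(3L, 9L, 15L, 21L), chrom_len = 30L)
  net <- distance_network(fx$table)
  expect_equal(unname(diag(net$dist)), rep(0, 3))
  expect_equal(net$dist, t(net$dist))
  expect_equal(net$dist["u", "v"], 0)          # duplicate samples
  expect_true(any(net$edges$weight == 0))
  # exhaustive check over the 3 possible spanning trees
  oracle <- bf_mst3(net$dist)
  expect_equal(sum(net$edges$weight), oracle$weight)
  set.seed(8)
  for (i in 1:5) {
    g3 <- matrix(sample(0:2, 60, replace = TRUE), 20,
                 dimnames = list(NULL, c("p", "q", "r")))
    fx3 <- tiny_fixture(g3, pos = 1:20 * 4, chrom_len = 100L, seed = i)
    net3 <- distance_network(fx3$table)
    expect_equal(sum(net3$edges$weight), bf_mst3(net3$dist)$weight)
  }
  # a pair with no co-called sites is undefined
  g4 <- cbind(a = c(1L, NA), b = c(NA, 1L), c = c(1L, 1L))
  fx4 <- tiny_fixture(g4, pos = c(5L, 10L), chrom_len = 20L)
  expect_true(is.na(distance_network(fx4$table)$dist["a", "b"]))
})
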