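#' Per-sample diversity summary stratified by constraint category
#'
#' For one sample, tallies within each annotation category (and overall):
#' the number of callable sites, cohort-polymorphic sites with a call in this
#' sample, heterozygotes, alternate homozygotes and derived allele copies,
#' and the two headline statistics: observed heterozygosity
#' \eqn{H_0 = n_{het} / n_{polymorphic}} and substitution rate
#' \eqn{D = (0.5 n_{het} + n_{homalt}) / n_{called}}.
#'
#' `n_sites_called` (the denominator of \eqn{D}) counts all callable reference
#' bases of the category inside the retained windows (the table holds only
#' polymorphic SNPs; monomorphic callable sites are implicitly reference
#' calls), minus this sample's missing calls. Polymorphic sites are those
#' segregating among the full retained cohort, matching a pipeline that keeps
#' only cohort-polymorphic SNPs.
#'
#' @param table A filtered (and ideally polarized) [genotype_table()].
#' @param ann A [site_annotation()].
#' @param sample Sample name.
#' @param cat_site,callable_bases optional precomputed per-site categories and
#'   per-category callable base counts (see [ann_category()],
#'   [category_bases()]); computed from `ann` when `NULL`. Passing them avoids
#'   recomputation when summarizing many samples of one table.
#' @return data.frame of class `diversity_summary` with one row per category
#'   plus `"all"`; zero denominators yield `NA` statistics.
#' @export
diversity_summary <- function(table, ann, sample, cat_site = NULL,
                              callable_bases = NULL) {
  stopifnot(inherits(table, "genotype_table"), sample %in% table$samples)
  if (is.null(cat_site))
    cat_site <- ann_category(ann, table$sites$chrom, table$sites$pos)
  g <- table$geno[, sample]
  dd <- g
  if (!is.null(table$derived_is_alt)) {
    fl <- which(!table$derived_is_alt)
    dd[fl] <- 2L - dd[fl]
  }
  if (is.null(callable_bases))
    callable_bases <- category_bases(ann, table$windows)
  rows <- lapply(c(CATEGORIES, "all"), function(cc) {
    in_cat <- if (cc == "all") rep(TRUE, length(g)) else cat_site == cc
    n_bases <- if (cc == "all") sum(callable_bases) else callable_bases[[cc]]
    called <- in_cat & !is.na(g)
    n_called_sites <- n_bases - sum(in_cat & is.na(g))
    n_poly <- sum(called)
    n_het <- sum(g[called] == 1L)
    n_homalt <- sum(g[called] == 2L)
    n_derived <- sum(dd[called])
    data.frame(
      sample = sample, category = cc,
      n_sites_called = n_called_sites, n_polymorphic = n_poly,
      n_het = n_het, n_homalt = n_homalt, n_derived = n_derived,
      H0 = if (n_poly > 0) n_het / n_poly else NA_real_,
      D = if (n_called_sites > 0) (0.5 * n_het + n_homalt) / n_called_sites
          else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

# derived allele copies per genotype call (0/1/2); unpolarized tables assume
# the ALT allele is derived (reference-as-ancestral convention)
derived_dose <- function(table) {
  d <- table$geno
  if (!is.null(table$derived_is_alt)) {
    flip <- which(!table$derived_is_alt)
    d[flip, ] <- 2L - d[flip, , drop = FALSE]
  }
  d
}

#' Callable reference bases per category
#'
#' Total reference bases of each annotation category, intersected with the
#' retained filter windows when given (the denominator source for the
#' substitution rate D).
#'
#' @param ann A [site_annotation()].
#' @param windows optional data.frame of retained windows (`chrom`, `start`,
#'   `end`, 0-based half-open), as recorded by [filter_sites()].
#' @return Named numeric vector over the five categories.
#' @export
category_bases <- function(ann, windows = NULL) {
  out <- setNames(numeric(length(CATEGORIES)), CATEGORIES)
  for (ch in names(ann$by_chrom)) {
    iv <- ann$by_chrom[[ch]]
    ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    chrlen <- ann$chrom_lengths[[ch]]
    if (!is.null(windows)) {
      w <- windows[windows$chrom == ch, , drop = FALSE]
      wr <- IRanges::reduce(IRanges::IRanges(start = w$start + 1L, end = w$end))
      # windows covering the whole chromosome are a no-op
      if (length(wr) == 1 && IRanges::start(wr) == 1 &&
          IRanges::end(wr) >= chrlen) windows_ch <- NULL else windows_ch <- w
    } else windows_ch <- NULL
    for (cc in CATEGORIES) {
      r <- ir[iv$category == cc]
      if (!is.null(windows_ch)) r <- IRanges::intersect(r, wr)
      out[cc] <- out[cc] + sum(IRanges::width(r))
    }
    # positions not covered by any interval count as "other"
    covered <- sum(IRanges::width(IRanges::reduce(ir)))
    if (is.null(windows_ch)) {
      out["other"] <- out["other"] + (chrlen - covered)
    } else {
      gap <- IRanges::setdiff(IRanges::IRanges(1L, chrlen), IRanges::reduce(ir))
      out["other"] <- out["other"] + sum(IRanges::width(IRanges::intersect(gap, wr)))
    }
  }
  out
}

#' Constrained-to-neutral substitution ratio
#'
#' Computes \eqn{d_{constrained}/d_{neutral}}: the derived-allele substitution
#' rate at phylogenetically constrained sites divided by that at 4-fold
#' degenerate (neutral) sites, together with the 2x2 allele counts, the
#' log-odds and its standard error (\eqn{\sqrt{\sum 1/cell}}), for use in
#' odds-ratio Z tests. Elevation of this ratio indicates relaxed purifying
#' selection.
#'
#' @param summary A [diversity_summary()].
#' @param constrained One or more constrained categories (`"0fold"`, `"CNS"`,
#'   `"CCS"`); several are pooled.
#' @return list of class `ratio_stat`: `constrained`, `cells` (derived and
#'   ancestral allele copies at constrained and 4-fold sites), `ratio`,
#'   `log_odds`, `se` (`NA` unless all four cells are positive).
#' @export
constrained_neutral_ratio <- function(summary,
                                      constrained = CONSTRAINED_CATEGORIES) {
  stopifnot(inherits(summary, "diversity_summary"),
            all(constrained %in% CONSTRAINED_CATEGORIES))
  pick <- function(cats) {
    s <- summary[summary$category %in% cats, , drop = FALSE]
    c(derived = sum(s$n_derived), total = 2 * sum(s$n_sites_called))
  }
  num <- pick(constrained)
  den <- pick("4fold")
  cells <- c(a = unname(num["derived"]), b = unname(num["total"] - num["derived"]),
             c = unname(den["derived"]), d = unname(den["total"] - den["derived"]))
  d_con <- if (num["total"] > 0) num["derived"] / num["total"] else NA_real_
  d_neu <- if (den["total"] > 0) den["derived"] / den["total"] else NA_real_
  ratio <- if (!is.na(d_neu) && d_neu > 0) unname(d_con / d_neu) else NA_real_
  ok <- all(cells > 0)
  structure(list(
    constrained = paste(constrained, collapse = "+"),
    sample = summary$sample[1],
    cells = cells,
    ratio = ratio,
    log_odds = if (ok) log(cells["a"] * cells["d"] / (cells["b"] * cells["c"]))
               else NA_real_,
    se = if (ok) sqrt(sum(1 / cells)) else NA_real_
  ), class = "ratio_stat")
}

#' @export
print.ratio_stat <- function(x, ...) {
  cat(sprintf("ratio_stat [%s] d_constrained/d_neutral = %.4g (logOR %.3g +/- %.3g)\n",
              x$constrained, x$ratio, x$log_odds, x$se))
  invisible(x)
}

#' Fisher's exact test on a 2x2 count table
#'
#' Exact two-sided hypergeometric P together with the sample odds ratio
#' \eqn{(a d)/(b c)} (`NA` when any cell is zero; the P value is still exact).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio`, `p_value`, and the log-odds `se`
#'   (\eqn{\sqrt{\sum 1/cell}}, `NA` on zero cells).
#' @export
fisher_pair_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(is.na(tab)) || any(tab < 0) || any(abs(tab - round(tab)) > 1e-8))
    stop("cells must be non-negative integers")
  tab <- round(tab)
  or <- if (all(tab > 0)) (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
        else NA_real_
  list(odds_ratio = or,
       p_value = stats::fisher.test(tab)$p.value,
       se = if (all(tab > 0)) sqrt(sum(1 / tab)) else NA_real_)
}

#' One-sided Z test for a difference of odds ratios
#'
#' Tests whether the odds underlying `stat_a` exceed those of `stat_b`:
#' \eqn{Z = (\log OR_A - \log OR_B)/\sqrt{SE_A^2 + SE_B^2}}, with the P value
#' from the upper tail of the standard normal (the one-sided convention
#' under which Z = 1.56 gives P = 0.059 and Z = 2.7 gives P = 0.003).
#'
#' @param stat_a,stat_b [constrained_neutral_ratio()] results (or any lists
#'   with `log_odds` and `se`).
#' @return list with `z` and one-sided `p_value` (`NA` if either SE is
#'   undefined).
#' @export
odds_ratio_z_test <- function(stat_a, stat_b) {
  if (is.na(stat_a$se) || is.na(stat_b$se))
    return(list(z = NA_real_, p_value = NA_real_))
  z <- (stat_a$log_odds - stat_b$log_odds) / sqrt(stat_a$se^2 + stat_b$se^2)
  list(z = unname(z), p_value = unname(stats::pnorm(z, lower.tail = FALSE)))
}

#' Windowed apomict heterozygosity versus sexual pairwise differences
#'
#' Splits the retained SNPs into non-overlapping windows of `window_snps`
#' consecutive sites (the trailing partial window is reported with its size)
#' and computes, per window, the apomict's observed heterozygosity and
#' \eqn{d_{ij}}: the mean over sexual sample pairs of the per-site expected
#' allele mismatch (0 for identical genotypes, 0.5 for heterozygote versus
#' either homozygote, 1 for opposite homozygotes), over co-called sites.
#'
#' @param table A filtered [genotype_table()].
#' @param ann A [site_annotation()] (reserved for category-restricted use).
#' @param sexual_samples At least two sexual sample names.
#' @param apomict_sample One apomict sample name.
#' @param window_snps SNPs per window (default 20000).
#' @return data.frame with one row per window: `window`, `chrom`, `start_pos`,
#'   `end_pos`, `n_snps`, `apomict_H0`, `sexual_dij`.
#' @export
window_profiles <- function(table, ann, sexual_samples, apomict_sample,
                            window_snps = 20000) {
  stopifnot(length(sexual_samples) >= 2,
            all(c(sexual_samples, apomict_sample) %in% table$samples))
  nsite <- n_sites(table)
  if (nsite == 0)
    return(data.frame(window = integer(0), chrom = character(0),
                      start_pos = integer(0), end_pos = integer(0),
                      n_snps = integer(0), apomict_H0 = numeric(0),
                      sexual_dij = numeric(0)))
  win <- (seq_len(nsite) - 1L) %/% as.integer(window_snps)
  ga <- table$geno[, apomict_sample]
  gs <- table$geno[, sexual_samples, drop = FALSE]
  pairs <- utils::combn(seq_along(sexual_samples), 2)
  # per-site mean pairwise mismatch, then averaged within window over pairs
  pair_diff <- matrix(NA_real_, nsite, ncol(pairs))
  for (k in seq_len(ncol(pairs)))
    pair_diff[, k] <- abs(gs[, pairs[1, k]] - gs[, pairs[2, k]]) / 2
  out <- lapply(split(seq_len(nsite), win), function(idx) {
    called <- !is.na(ga[idx])
    # per-pair proportion over co-called sites, then averaged across pairs
    per_pair <- colMeans(pair_diff[idx, , drop = FALSE], na.rm = TRUE)
    data.frame(
      window = win[idx[1]] + 1L,
      chrom = table$sites$chrom[idx[1]],
      start_pos = table$sites$pos[idx[1]],
      end_pos = table$sites$pos[idx[length(idx)]],
      n_snps = length(idx),
      apomict_H0 = if (any(called)) mean(ga[idx][called] == 1L) else NA_real_,
      sexual_dij = mean(per_pair, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Constrained/neutral ratios binned by derived-allele frequency in apomicts
#'
#' Assigns each site carrying at least one derived allele among the designated
#' apomicts to bin \eqn{n} = the number of apomict genotypes with a derived
#' allele, then computes \eqn{d_{constrained}/d_{neutral}} per bin separately
#' from the apomict calls and from the sexual calls at those same sites.
#' Within a bin, \eqn{d_{cat}} is the number of derived allele copies at the
#' bin's sites of that category over the total allele copies called at *all*
#' retained sites of the category (bin-restricted numerator, category-wide
#' denominator: restricting the denominator to the bin as well would cancel
#' the category composition signal and force every ratio to 1). Sites shared
#' by all apomicts (top bin) mostly reflect the hybrid origin or common
#' ancestry; intermediate bins expose post-origin mutation accumulation.
#'
#' @param table A polarized, filtered [genotype_table()].
#' @param ann A [site_annotation()].
#' @param apomict_samples The designated apomict set (bins run 1..length).
#' @param sexual_samples Sexual sample names.
#' @param constrained Constrained category (or categories, pooled).
#' @return data.frame, one row per bin: cells, ratios for both mating systems,
#'   one-sided Z and P for apomict excess.
#' @export
freq_binned_ratios <- function(table, ann, apomict_samples, sexual_samples,
                               constrained = "0fold") {
  stopifnot(all(c(apomict_samples, sexual_samples) %in% table$samples))
  dd <- derived_dose(table)
  da <- dd[, apomict_samples, drop = FALSE]
  ds <- dd[, sexual_samples, drop = FALSE]
  bin <- rowSums(da > 0, na.rm = TRUE)
  cat_site <- ann_category(ann, table$sites$chrom, table$sites$pos)
  is_con <- cat_site %in% constrained
  is_neu <- cat_site == "4fold"
  tot_con <- c(apo = 2 * sum(!is.na(da[is_con, , drop = FALSE])),
               sex = 2 * sum(!is.na(ds[is_con, , drop = FALSE])))
  tot_neu <- c(apo = 2 * sum(!is.na(da[is_neu, , drop = FALSE])),
               sex = 2 * sum(!is.na(ds[is_neu, , drop = FALSE])))
  rows <- lapply(seq_along(apomict_samples), function(b) {
    sel <- bin == b
    cells_of <- function(d, who) {
      con_der <- sum(d[sel & is_con, , drop = FALSE], na.rm = TRUE)
      neu_der <- sum(d[sel & is_neu, , drop = FALSE], na.rm = TRUE)
      c(a = con_der, b = unname(tot_con[who]) - con_der,
        c = neu_der, d = unname(tot_neu[who]) - neu_der)
    }
    ca <- cells_of(da, "apo")
    cs <- cells_of(ds, "sex")
    stat <- function(cells) {
      ok <- all(cells > 0)
      list(ratio = if (cells["a"] + cells["b"] > 0 && cells["c"] > 0)
             unname((cells["a"] / (cells["a"] + cells["b"])) /
                    (cells["c"] / (cells["c"] + cells["d"]))) else NA_real_,
           log_odds = if (ok)
             unname(log(cells["a"] * cells["d"] / (cells["b"] * cells["c"])))
             else NA_real_,
           se = if (ok) unname(sqrt(sum(1 / cells))) else NA_real_)
    }
    za <- stat(ca)
    zs <- stat(cs)
    zz <- odds_ratio_z_test(za, zs)
    data.frame(bin = b, n_sites = sum(sel),
               apo_a = ca["a"], apo_b = ca["b"], apo_c = ca["c"], apo_d = ca["d"],
               sex_a = cs["a"], sex_b = cs["b"], sex_c = cs["c"], sex_d = cs["d"],
               ratio_apo = za$ratio, ratio_sex = zs$ratio,
               z = zz$z, p_value = zz$p_value, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Pairwise genetic distances and minimum spanning network
#'
#' Distance between two samples is the mean per-site allele-sharing difference
#' over co-called sites (0 identical genotypes, 0.5 one shared allele, 1 no
#' shared allele). The network is the minimum spanning tree of the distance
#' matrix (Prim's algorithm, deterministic tie-break by sample order).
#'
#' @param table A [genotype_table()].
#' @param samples Samples to include (default all).
#' @return list with `dist` (symmetric matrix, `NA` where a pair shares no
#'   co-called site) and `edges` (data.frame `from`, `to`, `weight`).
#' @export
distance_network <- function(table, samples = table$samples) {
  stopifnot(length(samples) >= 2, all(samples %in% table$samples))
  g <- table$geno[, samples, drop = FALSE]
  m <- length(samples)
  d <- matrix(0, m, m, dimnames = list(samples, samples))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    co <- !is.na(g[, i]) & !is.na(g[, j])
    d[i, j] <- d[j, i] <- if (any(co)) mean(abs(g[co, i] - g[co, j]) / 2)
                          else NA_real_
  }
  # Prim's MST; ties broken by sample order (first minimal edge wins)
  in_tree <- c(TRUE, rep(FALSE, m - 1))
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0))
  for (step in seq_len(m - 1)) {
    best <- c(NA, NA)
    bw <- Inf
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      w <- d[i, j]
      if (!is.na(w) && w < bw) { bw <- w; best <- c(i, j) }
    }
    if (!is.finite(bw)) stop("distance graph is disconnected (no co-called sites)")
    in_tree[best[2]] <- TRUE
    edges <- rbind(edges, data.frame(from = samples[best[1]],
                                     to = samples[best[2]], weight = bw))
  }
  list(dist = d, edges = edges)
}
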