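#' Pipeline configuration
#'
#' Bundles input locations (or simulation parameters), filter thresholds and
#' tree-analysis settings for [run_pipeline()]. Exactly one of `sim` or the
#' four input paths must be supplied.
#'
#' @param vcf,bed,fasta,samples,blocks Input paths (see [read_inputs()],
#'   [read_phased_blocks()]).
#' @param sim list of [sim_params()] arguments for a simulated run.
#' @param site_qual_min,gt_qual_min,window_bp Quality filters (defaults 15,
#'   40, 20000).
#' @param min_callable_frac Window callable fraction (default 0.30 for file
#'   input; 0 for simulated cohorts, whose VCFs hold variant records only, so
#'   the all-sites callable fraction is not represented).
#' @param window_snps SNPs per diversity window (default 20000).
#' @param bootstrap_reps Bootstrap replicates per tree (default 100; 0
#'   disables bootstrapping and the support filter).
#' @param min_support,z_max Tree filters (defaults 70, 3; see
#'   [filter_trees()]).
#' @param min_columns Minimum usable alignment columns per region (default
#'   500).
#' @param estimate_alpha Estimate the Gamma shape per alignment (default
#'   TRUE).
#' @param gamma_k Discrete-Gamma categories (default 4; `gamma_k = 1` with
#'   `estimate_alpha = FALSE` gives plain GTR, the fast setting for large
#'   simulation studies whose generator has no within-category rate
#'   variation).
#' @param constrained Constrained category for the terminal contrasts
#'   (default `"0fold"`).
#' @param freq_bin_exclude Populations whose apomicts are excluded from the
#'   derived-allele-frequency binning (e.g. a lineage with a different
#'   hybridizing parent); default none.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, bed = NULL, fasta = NULL,
                            samples = NULL, blocks = NULL, sim = NULL,
                            site_qual_min = 15, gt_qual_min = 40,
                            window_bp = 20000, min_callable_frac = NULL,
                            window_snps = 20000, bootstrap_reps = 100,
                            min_support = 70, z_max = 3, min_columns = 500,
                            estimate_alpha = TRUE, gamma_k = 4,
                            constrained = "0fold",
                            freq_bin_exclude = character(0), seed = 1,
                            out_dir = tempfile("apomacc_run_")) {
  have_files <- !is.null(vcf)
  if (is.null(sim) && !have_files)
    stop("config must supply either 'sim' parameters or input path 'vcf' ",
         "(with 'bed', 'fasta', 'samples', 'blocks')")
  if (have_files)
    for (f in c("bed", "fasta", "samples", "blocks"))
      if (is.null(get(f))) stop("config is missing input path field '", f, "'")
  if (is.null(min_callable_frac)) min_callable_frac <- if (have_files) 0.30 else 0
  stopifnot(site_qual_min >= 0, gt_qual_min >= 0, window_bp > 0,
            min_callable_frac >= 0, min_callable_frac <= 1, window_snps > 0,
            bootstrap_reps >= 0, min_support >= 0, z_max > 0)
  structure(list(vcf = vcf, bed = bed, fasta = fasta, samples = samples,
                 blocks = blocks, sim = sim,
                 site_qual_min = site_qual_min, gt_qual_min = gt_qual_min,
                 window_bp = window_bp, min_callable_frac = min_callable_frac,
                 window_snps = window_snps, bootstrap_reps = bootstrap_reps,
                 min_support = min_support, z_max = z_max,
                 min_columns = min_columns, estimate_alpha = estimate_alpha,
                 gamma_k = gamma_k, constrained = constrained,
                 freq_bin_exclude = freq_bin_exclude,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# deterministic sub-seed derivation, kept below 2^31
sub_seed <- function(seed, k) as.integer((as.double(seed) * 7919 + k) %% 2147483647)

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> filter -> polarize -> diversity statistics and
#' pair tests -> window profiles and distance network -> five-taxon trees
#' (fit, bootstrap, filter, classify) -> terminal contrasts and ratio test.
#' Per-stage tables are written as TSV under `config$out_dir` together with a
#' `summary.json` and a `config.json` snapshot; progress is logged to stderr.
#' Outputs are pure functions of (inputs, config, seed).
#'
#' @param config A [pipeline_config()].
#' @param stages Run the pipeline only through the given final stage
#'   (`"filter"`, `"diversity"`, `"trees"` or `"contrasts"`, the default).
#' @return list report (also serialized to `summary.json`): filter log,
#'   per-sample diversity, per-pair tests, topology summary, contrasts,
#'   branch-length ratio test; `empty = TRUE` if filtering removed all sites.
#' @export
run_pipeline <- function(config, stages = "contrasts") {
  stopifnot(inherits(config, "pipeline_config"))
  stage_order <- c("filter", "diversity", "trees", "contrasts")
  last <- match.arg(stages, stage_order)
  run_to <- match(last, stage_order)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  report <- list(seed = config$seed)

  ## ---- acquire ----
  if (!is.null(config$sim)) {
    message("[simulate] generating cohort (seed ", config$seed, ")")
    params <- do.call(sim_params, modifyList(config$sim,
                                             list(seed = config$seed)))
    cohort <- simulate_cohort(params)
    table <- cohort$table; ann <- cohort$ann; sheet <- cohort$samples
    blocks <- cohort$blocks
    reference <- cohort$reference
  } else {
    message("[read] ", config$vcf)
    inp <- read_inputs(config$vcf, config$bed, config$fasta, config$samples)
    table <- inp$table; ann <- inp$ann; sheet <- inp$samples
    blocks <- read_phased_blocks(config$blocks)
    reference <- ann$sequence
  }
  report$n_input_sites <- n_sites(table)

  ## ---- filter + polarize ----
  message("[filter] site_qual>=", config$site_qual_min, " gq>=",
          config$gt_qual_min, " window=", config$window_bp, "bp frac>=",
          config$min_callable_frac)
  table <- withCallingHandlers(
    filter_sites(table, config$site_qual_min, config$gt_qual_min,
                 config$window_bp, config$min_callable_frac),
    apomacc_empty_result = function(w) invokeRestart("muffleWarning"))
  table <- polarize_derived(table, ann)
  for (l in table$log) message("[filter] ", l)
  report$filter_log <- table$log
  report$n_retained_sites <- n_sites(table)
  report$missingness <- missingness_report(table)
  if (n_sites(table) == 0) {
    report$empty <- TRUE
    message("[filter] empty result: no sites retained")
    jsonlite::write_json(report, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(report))
  }
  report$empty <- FALSE
  if (run_to < 2) return(finish_report(report, table, config))

  ## ---- diversity ----
  message("[diversity] per-sample summaries and pair tests")
  cat_site <- ann_category(ann, table$sites$chrom, table$sites$pos)
  callable <- category_bases(ann, table$windows)
  summaries <- lapply(setNames(nm = table$samples), function(s)
    diversity_summary(table, ann, s, cat_site, callable))
  div_tab <- do.call(rbind, summaries)
  utils::write.table(div_tab, file.path(config$out_dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pair_tests <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i) {
    sx <- summaries[[sheet$sexual[i]]]
    ap <- summaries[[sheet$apomict[i]]]
    all_s <- function(su) su[su$category == "all", ]
    h0 <- fisher_pair_test(rbind(
      c(all_s(ap)$n_het, all_s(ap)$n_polymorphic - all_s(ap)$n_het),
      c(all_s(sx)$n_het, all_s(sx)$n_polymorphic - all_s(sx)$n_het)))
    dd <- fisher_pair_test(rbind(
      c(all_s(ap)$n_derived, 2 * all_s(ap)$n_sites_called - all_s(ap)$n_derived),
      c(all_s(sx)$n_derived, 2 * all_s(sx)$n_sites_called - all_s(sx)$n_derived)))
    ratio_rows <- do.call(rbind, lapply(CONSTRAINED_CATEGORIES, function(cc) {
      za <- constrained_neutral_ratio(ap, cc)
      zs <- constrained_neutral_ratio(sx, cc)
      zt <- odds_ratio_z_test(za, zs)
      data.frame(population = sheet$population[i],
                 statistic = paste0("ratio_", cc),
                 apomict = za$ratio, sexual = zs$ratio,
                 or = if (!is.na(za$log_odds) && !is.na(zs$log_odds))
                        exp(za$log_odds - zs$log_odds) else NA_real_,
                 z = zt$z, p_value = zt$p_value)
    }))
    rbind(data.frame(population = sheet$population[i], statistic = "H0",
                     apomict = all_s(ap)$H0, sexual = all_s(sx)$H0,
                     or = h0$odds_ratio, z = NA_real_, p_value = h0$p_value),
          data.frame(population = sheet$population[i], statistic = "D",
                     apomict = all_s(ap)$D, sexual = all_s(sx)$D,
                     or = dd$odds_ratio, z = NA_real_, p_value = dd$p_value),
          ratio_rows)
  }))
  utils::write.table(pair_tests, file.path(config$out_dir, "pair_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$pair_tests <- pair_tests

  # cohort-level ratio test: pooled counts are descriptive only — mutations
  # shared through hybrid origins / the species stem enter once per carrier,
  # so the naive log-odds SE understates the pooled variance; the calibrated
  # comparisons are the per-pair tests above (see the methods vignette)
  pool <- function(samps) {
    su <- do.call(rbind, summaries[samps])
    agg <- stats::aggregate(su[c("n_sites_called", "n_polymorphic", "n_het",
                                 "n_homalt", "n_derived")],
                            by = list(category = su$category), FUN = sum)
    agg$sample <- "pooled"
    agg$H0 <- ifelse(agg$n_polymorphic > 0, agg$n_het / agg$n_polymorphic, NA)
    agg$D <- ifelse(agg$n_sites_called > 0,
                    (0.5 * agg$n_het + agg$n_homalt) / agg$n_sites_called, NA)
    class(agg) <- c("diversity_summary", "data.frame")
    agg
  }
  apo_pool <- pool(sheet$apomict)
  sex_pool <- pool(sheet$sexual)
  report$cohort_ratio_tests <- do.call(rbind, lapply(
    CONSTRAINED_CATEGORIES, function(cc) {
      zt <- odds_ratio_z_test(constrained_neutral_ratio(apo_pool, cc),
                              constrained_neutral_ratio(sex_pool, cc))
      data.frame(constrained = cc,
                 ratio_apomict = constrained_neutral_ratio(apo_pool, cc)$ratio,
                 ratio_sexual = constrained_neutral_ratio(sex_pool, cc)$ratio,
                 z = zt$z, p_value = zt$p_value)
    }))
  report$H0 <- c(apomict = apo_pool$H0[apo_pool$category == "all"],
                 sexual = sex_pool$H0[sex_pool$category == "all"])
  report$D <- c(apomict = apo_pool$D[apo_pool$category == "all"],
                sexual = sex_pool$D[sex_pool$category == "all"])

  message("[diversity] windows and distance network")
  win <- do.call(rbind, lapply(seq_len(nrow(sheet)), function(i) {
    w <- window_profiles(table, ann, sheet$sexual, sheet$apomict[i],
                         config$window_snps)
    if (nrow(w) > 0) w$population <- sheet$population[i]
    w
  }))
  utils::write.table(win, file.path(config$out_dir, "windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  net <- distance_network(table)
  utils::write.table(data.frame(sample = rownames(net$dist),
                                round(net$dist, 6)),
                     file.path(config$out_dir, "distance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, file.path(config$out_dir, "network_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  apo_bins <- setdiff(sheet$apomict,
                      sheet$apomict[sheet$population %in% config$freq_bin_exclude])
  report$freq_binned <- freq_binned_ratios(table, ann, apo_bins, sheet$sexual,
                                           constrained = config$constrained)
  if (run_to < 3) return(finish_report(report, table, config))

  ## ---- trees ----
  message("[trees] fitting five-taxon trees over ",
          nrow(blocks), " phased blocks")
  ctl <- list(estimate_alpha = config$estimate_alpha, k = config$gamma_k,
              init_alpha = if (config$gamma_k == 1) Inf else 1,
              min_columns = config$min_columns)
  results <- list()
  for (i in seq_len(nrow(blocks))) {
    blockrow <- blocks[i, ]
    pop <- sheet$population[match(blockrow$sample, sheet$apomict)]
    if (is.na(pop)) next
    sx <- sheet$sexual[sheet$population == pop]
    pseudo <- make_pseudo_haplotypes(table, reference, sx,
                                     list(chrom = blockrow$chrom,
                                          start = blockrow$start,
                                          end = blockrow$end),
                                     seed = sub_seed(config$seed, i))
    aln <- assemble_alignment(blockrow, pseudo, reference, ann)
    if (is.null(aln)) next
    tr <- fit_ml_tree(aln, control = ctl)
    if (config$bootstrap_reps > 0)
      tr <- bootstrap_support(aln, tr, n_reps = config$bootstrap_reps,
                              seed = sub_seed(config$seed, 100000 + i))
    tr$sample <- blockrow$sample
    tr$aln <- aln
    results[[length(results) + 1L]] <- tr
  }
  if (length(results) == 0) {
    report$empty_trees <- TRUE
    return(finish_report(report, table, config))
  }
  passing <- filter_trees(results,
                          min_support = if (config$bootstrap_reps > 0)
                            config$min_support else 0,
                          z_max = config$z_max)
  report$tree_filter <- as.list(attr(passing, "filter_log"))
  message("[trees] ", report$tree_filter$passing, "/",
          report$tree_filter$n, " trees pass filters")
  if (length(passing) == 0) {
    report$empty_trees <- TRUE
    return(finish_report(report, table, config))
  }
  tabs <- lapply(passing, function(tr) assign_branch_mutations(tr, tr$aln))
  topo_sum <- summarize_topologies(tabs)
  report$topology <- list(classes = topo_sum$table,
                          origin = as.list(topo_sum$origin), n = topo_sum$n)
  tree_tab <- do.call(rbind, lapply(seq_along(passing), function(j) {
    tr <- passing[[j]]; bm <- tabs[[j]]
    data.frame(sample = tr$sample, chrom = tr$region$chrom,
               start = tr$region$start, end = tr$region$end,
               topology = tr$topology, class = bm$class$class,
               origin = bm$class$origin,
               conspecific = if (is.na(bm$conspecific$tip)) "ambiguous"
                             else bm$conspecific$tip,
               loglik = tr$loglik, n_columns = tr$n_columns,
               min_support = if (is.null(tr$supports)) NA_real_
                             else min(tr$supports),
               newick = tree_newick(tr))
  }))
  utils::write.table(tree_tab, file.path(config$out_dir, "trees.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(tree_tab$newick, file.path(config$out_dir, "trees.nwk"))
  if (run_to < 4) return(finish_report(report, table, config))

  ## ---- contrasts ----
  message("[contrasts] terminal-branch contrasts (",
          config$constrained, " vs 4fold)")
  report$contrasts <- tryCatch(
    terminal_contrasts(tabs, constrained = config$constrained),
    error = function(e) { message("[contrasts] ", conditionMessage(e)); NULL })
  if (!is.null(report$contrasts))
    utils::write.table(report$contrasts,
                       file.path(config$out_dir, "contrasts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  report$ratio_test <- branch_length_ratio_test(tabs)
  finish_report(report, table, config)
}

finish_report <- function(report, table, config) {
  jsonlite::write_json(report, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a simulated cohort),
#' `filter`/`diversity`/`trees`/`run-all` (run the pipeline through the given
#' stage). Options: `--config <json>`, `--out <dir>`, `--seed <int>`, plus
#' `--no-bootstrap` to disable tree bootstrapping. Logs go to stderr, data to
#' files; returns exit status 0 on success, 3 on an empty result.
#'
#' @param args Character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
apomacc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: apomacc <simulate|filter|diversity|trees|run-all> ",
            "[--config file.json] [--out dir] [--seed n] [--no-bootstrap]")
    return(invisible(2L))
  }
  cmd <- args[1]
  opt <- list(config = NULL, out = NULL, seed = NULL,
              bootstrap = TRUE)
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--config") { opt$config <- args[i + 1]; i <- i + 2 }
    else if (a == "--out") { opt$out <- args[i + 1]; i <- i + 2 }
    else if (a == "--seed") { opt$seed <- as.integer(args[i + 1]); i <- i + 2 }
    else if (a == "--no-bootstrap") { opt$bootstrap <- FALSE; i <- i + 1 }
    else if (a == "--threads") i <- i + 2   # accepted; computation is serial
    else stop("unknown option: ", a)
  }
  fields <- if (!is.null(opt$config))
    jsonlite::read_json(opt$config, simplifyVector = TRUE) else list()
  if (!is.null(opt$seed)) fields$seed <- opt$seed
  if (!is.null(opt$out)) fields$out_dir <- opt$out
  if (!isTRUE(opt$bootstrap)) fields$bootstrap_reps <- 0
  if (cmd == "simulate") {
    sp <- do.call(sim_params, c(fields$sim,
                                if (!is.null(fields$seed))
                                  list(seed = fields$seed)))
    out <- if (!is.null(fields$out_dir)) fields$out_dir else "cohort"
    write_cohort(simulate_cohort(sp), out)
    message("cohort written to ", out)
    return(invisible(0L))
  }
  stage <- switch(cmd, filter = "filter", diversity = "diversity",
                  trees = "trees", classify = "trees", contrasts = "contrasts",
                  `run-all` = "contrasts",
                  stop("unknown subcommand: ", cmd))
  config <- do.call(pipeline_config, fields)
  report <- run_pipeline(config, stages = stage)
  invisible(if (isTRUE(report$empty)) 3L else 0L)
}
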