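#' Simulate a sexual/apomict resequencing cohort with a full truth log
#'
#' Generates a reference genome, a category annotation laid down in contiguous
#' runs, diploid genotypes for one sexual and one apomict per population,
#' phased apomict haplotype blocks, and a truth log recording every planted
#' mutation.
#'
#' The generative model (hybrid mode): all lineages descend from a common
#' ancestor whose sequence is the reference (and serves as the outgroup).
#' A species stem carrying `hybrid_divergence/2` substitutions/site separates
#' the sampled species from its sister; its mutations are homozygous in every
#' sexual and carried on the conspecific haplotype of every apomict. Each of
#' `n_hybrid_origins` hybridization events pairs that conspecific lineage with
#' a sister-species founder haplotype carrying the other `hybrid_divergence/2`
#' (never segregating in sexuals, so fixed heterozygous in its apomicts).
#' Apomicts sharing an origin are related by a seeded coalescent clone
#' genealogy of height `1 - origin_time` lifetimes; mutations accumulate on
#' both non-recombining haplotypes along its edges at rate `mu` per lifetime,
#' with constrained-site retention `relax_factor_rho x retain_constrained_sex`.
#' Sexual lineages are independent draws from the ancestor at rate `mu` with
#' sexual retention; each mutation is homozygous with probability `selfing_F`
#' (so expected heterozygosity is depressed by the factor `1 - selfing_F`).
#' Mutation placement is per-category Poisson with uniform placement inside
#' category runs and infinite-sites within a run (positions drawn without
#' replacement).
#'
#' In `origin_mode = "within"` there is no sister species: each apomict is
#' founded from a deep haplotype lineage of its sympatric sexual population
#' (rate `d_poly` of shared heterozygous sites), carries founder homozygous
#' mutations (`origin_time * mu`), and then accumulates post-origin mutations
#' independently on each haplotype.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `sim_cohort` with elements `params`, `reference`
#'   (named character), `ann` ([site_annotation()]), `table`
#'   ([genotype_table()]), `blocks` (data.frame of phased apomict haplotype
#'   blocks), `samples` (sample sheet) and `truth` (see Details).
#'   `truth` holds `origins` (apomict -> origin event), `mutations` (one row
#'   per planted mutation: position, category, class, derived base),
#'   `carriers` (mutation x sample x haplotype), `lineage_counts` (per-lineage
#'   derived-mutation counts by category, haplotype and class) and `blocks`
#'   (which emitted haplotype of each phased block is the conspecific one).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  L <- params$genome_length
  chrom <- "chr1"
  bases <- c("A", "C", "G", "T")
  ref_chars <- sample(bases, L, replace = TRUE)

  ## ---- annotation: contiguous category runs ----
  abp <- params$annotation_block_bp
  nb <- as.integer(ceiling(L / abp))
  run_cat <- sample(CATEGORIES, nb, replace = TRUE,
                    prob = params$annotation_fractions)
  run_start <- (seq_len(nb) - 1L) * abp
  run_end <- pmin(run_start + abp, L)
  new_run <- c(TRUE, run_cat[-1] != run_cat[-nb])
  run_id <- cumsum(new_run)
  iv <- data.frame(
    chrom = chrom,
    start = run_start[new_run],
    end = as.integer(tapply(run_end, run_id, max)),
    category = run_cat[new_run], stringsAsFactors = FALSE)
  cat_at <- rep(run_cat, times = run_end - run_start)
  pos_by_cat <- split(seq_len(L), factor(cat_at, levels = CATEGORIES))
  n_cat <- vapply(pos_by_cat, length, integer(1))

  ## ---- samples ----
  n <- params$n_pops
  pops <- paste0("pop", seq_len(n))
  sex_names <- paste0("sex_", pops)
  apo_names <- paste0("apo_", pops)
  samp_names <- c(sex_names, apo_names)
  ns <- length(samp_names)
  sex_sid <- seq_len(n)
  apo_sid <- n + seq_len(n)
  sheet <- data.frame(population = pops, sexual = sex_names,
                      apomict = apo_names, stringsAsFactors = FALSE)

  # origin assignment: origin 1 takes the leading populations, each remaining
  # origin gets one population of its own (a large shared cluster plus
  # divergent singletons, as seen in real apomict complexes)
  k <- params$n_hybrid_origins
  origin_of <- c(rep(1L, n - (k - 1L)), seq_len(k)[-1][seq_len(k - 1L)])
  origins <- data.frame(sample = apo_names, origin = origin_of,
                        stringsAsFactors = FALSE)

  ret <- retention_probs(params)
  ot <- params$origin_time

  ## ---- event plan ----
  # each event: mutation class, per-site rate (before retention), selection
  # regime, and the (sample, haplotype) carrier set
  events <- list()
  ev <- function(class, rate, regime, sid, hap, origin = NA_integer_,
                 pop = NA_character_, zygosity_draw = FALSE) {
    list(class = class, rate = rate, regime = regime,
         sid = sid, hap = hap, origin = origin, pop = pop,
         zygosity_draw = zygosity_draw)
  }
  if (params$origin_mode == "hybrid") {
    events[[length(events) + 1L]] <- ev(
      "species_trunk", params$hybrid_divergence / 2, "sex",
      sid = c(sex_sid, sex_sid, apo_sid),
      hap = c(rep(1L, n), rep(2L, n), rep(1L, n)))
    for (e in seq_len(k)) {
      mem <- apo_sid[origin_of == e]
      events[[length(events) + 1L]] <- ev(
        "founder_divergence", params$hybrid_divergence / 2, "sex",
        sid = mem, hap = rep(2L, length(mem)), origin = e)
      events[[length(events) + 1L]] <- ev(
        "origin_stem", ot * params$mu, "sex",
        sid = mem, hap = rep(1L, length(mem)), origin = e)
      gen <- coalescent_edges(length(mem))
      for (h in 1:2) {
        for (j in seq_len(nrow(gen))) {
          tips <- mem[gen$tip[[j]]]
          events[[length(events) + 1L]] <- ev(
            if (gen$is_tip[j]) "apo_private" else "apo_shared",
            gen$len[j] * (1 - ot) * params$mu, "apo",
            sid = tips, hap = rep(h, length(tips)), origin = e)
        }
      }
    }
  } else {  # within-species origin: founder drawn from the sympatric sexual
    for (p in seq_len(n)) {
      events[[length(events) + 1L]] <- ev(
        "deep_poly", params$d_poly, "sex",
        sid = c(sex_sid[p], apo_sid[p], apo_sid[p]), hap = c(1L, 1L, 2L),
        pop = pops[p])
      events[[length(events) + 1L]] <- ev(
        "founder_hom", ot * params$mu, "sex",
        sid = c(apo_sid[p], apo_sid[p]), hap = c(1L, 2L), pop = pops[p],
        origin = p)
      for (h in 1:2)
        events[[length(events) + 1L]] <- ev(
          "apo_private", (1 - ot) * params$mu, "apo",
          sid = apo_sid[p], hap = h, pop = pops[p], origin = p)
    }
  }
  for (p in seq_len(n))
    events[[length(events) + 1L]] <- ev(
      "sexual_lineage", params$mu, "sex", sid = sex_sid[p], hap = NA_integer_,
      pop = pops[p], zygosity_draw = TRUE)

  ## ---- draw mutation counts and positions ----
  ne <- length(events)
  lambda <- matrix(0, ne, length(CATEGORIES),
                   dimnames = list(NULL, CATEGORIES))
  for (i in seq_len(ne))
    lambda[i, ] <- events[[i]]$rate * ret[[events[[i]]$regime]] * n_cat
  counts <- matrix(rpois(length(lambda), lambda), ne,
                   dimnames = dimnames(lambda))
  mut_list <- vector("list", length(CATEGORIES))
  for (ci in seq_along(CATEGORIES)) {
    tot <- sum(counts[, ci])
    if (tot == 0) next
    if (tot > n_cat[ci])
      stop("genome too short: ", tot, " mutations requested for ",
           CATEGORIES[ci], " but only ", n_cat[ci], " sites available")
    pp <- sample(pos_by_cat[[ci]], tot)   # infinite sites: no replacement
    mut_list[[ci]] <- data.frame(pos = pp, cat = CATEGORIES[ci],
                                 event = rep(seq_len(ne), counts[, ci]),
                                 stringsAsFactors = FALSE)
  }
  mut <- do.call(rbind, mut_list)
  if (is.null(mut)) mut <- data.frame(pos = integer(0), cat = character(0),
                                      event = integer(0))
  mut <- mut[order(mut$event, mut$pos), , drop = FALSE]
  nm <- nrow(mut)
  ev_class <- vapply(events, `[[`, "", "class")
  ev_origin <- vapply(events, `[[`, NA_integer_, "origin")
  ev_pop <- vapply(events, `[[`, NA_character_, "pop")
  mut$class <- ev_class[mut$event]
  mut$origin <- ev_origin[mut$event]
  mut$pop <- ev_pop[mut$event]
  ref_idx <- match(ref_chars[mut$pos], bases)
  mut$base <- bases[(ref_idx - 1L + sample.int(3L, nm, replace = TRUE)) %% 4L + 1L]
  mut$zygosity <- rep(NA_character_, nm)

  ## ---- carriers ----
  carr_list <- vector("list", ne)
  for (i in seq_len(ne)) {
    rows <- which(mut$event == i)
    m <- length(rows)
    if (m == 0) next
    e <- events[[i]]
    if (e$zygosity_draw) {
      hom <- runif(m) < params$selfing_F
      mut$zygosity[rows] <- ifelse(hom, "hom", "het")
      het_hap <- sample(1:2, m, replace = TRUE)
      carr_list[[i]] <- data.frame(
        mut = c(rows, rows[hom]),
        sid = e$sid,
        hap = c(ifelse(hom, 1L, het_hap), rep(2L, sum(hom))))
    } else {
      nc <- length(e$sid)
      carr_list[[i]] <- data.frame(
        mut = rep(rows, times = nc),
        sid = rep(e$sid, each = m),
        hap = rep(e$hap, each = m))
    }
  }
  carriers <- if (nm > 0) do.call(rbind, carr_list) else
    data.frame(mut = integer(0), sid = integer(0), hap = integer(0))

  ## ---- genotype table ----
  o <- order(mut$pos)
  site_of_mut <- integer(nm)
  site_of_mut[o] <- seq_len(nm)
  nsite <- nm
  dose_key <- (carriers$sid - 1L) * nsite + site_of_mut[carriers$mut]
  geno <- matrix(tabulate(dose_key, nbins = nsite * ns), nrow = nsite,
                 ncol = ns, dimnames = list(NULL, samp_names))
  storage.mode(geno) <- "integer"
  sites <- data.frame(chrom = rep(chrom, nsite), pos = mut$pos[o],
                      ref = ref_chars[mut$pos[o]], alt = mut$base[o],
                      qual = round(runif(nsite, 100, 999), 1),
                      stringsAsFactors = FALSE)
  gq <- matrix(sample(60L:99L, nsite * ns, replace = TRUE), nsite, ns,
               dimnames = list(NULL, samp_names))
  poly <- is_polymorphic(geno)
  # sites are sorted and unique by construction; skip constructor validation
  table <- structure(list(sites = sites[poly, , drop = FALSE],
                          geno = geno[poly, , drop = FALSE],
                          gq = gq[poly, , drop = FALSE],
                          samples = samp_names,
                          chrom_lengths = setNames(L, chrom),
                          derived_is_alt = NULL, windows = NULL,
                          log = character(0)),
                     class = "genotype_table")
  rownames(table$sites) <- NULL

  ## ---- phased apomict haplotype blocks ----
  bb <- params$block_bp
  nbk <- params$n_blocks
  block_start <- if (nbk == 1) as.integer((L - bb) %/% 2L) else
    as.integer(floor(seq(0, L - bb, length.out = nbk)))
  hap_pos <- hap_base <- vector("list", ns)
  mpos <- mut$pos
  for (sid in apo_sid) {
    sel <- carriers$sid == sid
    hap_pos[[sid]] <- split(mpos[carriers$mut[sel]], carriers$hap[sel])
    hap_base[[sid]] <- split(mut$base[carriers$mut[sel]], carriers$hap[sel])
  }
  blk <- vector("list", n * nbk)
  blk_truth <- vector("list", n * nbk)
  bi <- 0L
  for (p in seq_len(n)) {
    sid <- apo_sid[p]
    swap <- runif(nbk) < 0.5
    for (b in seq_len(nbk)) {
      st <- block_start[b]
      s <- vector("list", 2)
      for (h in 1:2) {
        chars <- ref_chars[(st + 1L):(st + bb)]
        pp <- hap_pos[[sid]][[as.character(h)]]
        bs <- hap_base[[sid]][[as.character(h)]]
        in_blk <- which(pp > st & pp <= st + bb)
        chars[pp[in_blk] - st] <- bs[in_blk]
        s[[h]] <- paste(chars, collapse = "")
      }
      if (swap[b]) s <- s[2:1]
      bi <- bi + 1L
      blk[[bi]] <- data.frame(sample = apo_names[p], chrom = chrom,
                              start = st, end = st + bb,
                              hap1 = s[[1]], hap2 = s[[2]],
                              stringsAsFactors = FALSE)
      blk_truth[[bi]] <- data.frame(
        sample = apo_names[p], block = b, start = st, end = st + bb,
        conspecific_hap = if (params$origin_mode == "hybrid")
          ifelse(swap[b], 2L, 1L) else NA_integer_)
    }
  }
  blocks <- do.call(rbind, blk)
  if (is.null(blocks))
    blocks <- data.frame(sample = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         hap1 = character(0), hap2 = character(0))

  ## ---- truth log ----
  mut_out <- mut[c("pos", "cat", "class", "origin", "pop", "base", "zygosity")]
  mut_out$sample_private <- rep(NA_character_, nm)
  priv <- mut$class %in% c("sexual_lineage")
  mut_out$sample_private[priv] <- sex_names[match(mut$pop[priv], pops)]
  carriers_out <- data.frame(mut = carriers$mut,
                             sample = samp_names[carriers$sid],
                             hap = carriers$hap, stringsAsFactors = FALSE)
  lc <- carriers_out
  lc$cat <- mut$cat[lc$mut]
  lc$class <- mut$class[lc$mut]
  lineage_counts <- as.data.frame(
    table(sample = lc$sample, hap = lc$hap, cat = lc$cat, class = lc$class),
    responseName = "count", stringsAsFactors = FALSE)
  lineage_counts <- lineage_counts[lineage_counts$count > 0, , drop = FALSE]
  rownames(lineage_counts) <- NULL

  ref_string <- setNames(paste(ref_chars, collapse = ""), chrom)
  structure(list(
    params = params,
    reference = ref_string,
    ann = new_site_annotation(iv, ref_string,
                              setNames(list(ref_chars), chrom)),
    table = table,
    blocks = blocks,
    samples = sheet,
    truth = list(seed = params$seed, origins = origins, mutations = mut_out,
                 carriers = carriers_out, lineage_counts = lineage_counts,
                 blocks = do.call(rbind, blk_truth),
                 n_monomorphic_dropped = sum(!poly))
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", x$params$n_pops, "population pairs,",
      n_sites(x$table), "polymorphic sites,", nrow(x$blocks),
      "phased blocks (seed ", x$params$seed, ")\n", sep = " ")
  invisible(x)
}

# Kingman coalescent clone genealogy over n tips, edge lengths scaled so the
# root-to-tip height is 1; one row per edge with the tip set below it.
coalescent_edges <- function(n) {
  if (n == 1)
    return(data.frame(len = 1, tip = I(list(1L)), is_tip = TRUE))
  height <- numeric(2 * n - 1)
  tipsets <- c(as.list(seq_len(n)), vector("list", n - 1))
  parent <- integer(2 * n - 2)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  for (k in seq(n, 2)) {
    t <- t + rexp(1, k * (k - 1) / 2)
    pair <- sample(active, 2)
    height[nxt] <- t
    tipsets[[nxt]] <- sort(c(tipsets[[pair[1]]], tipsets[[pair[2]]]))
    parent[pair] <- nxt
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  child <- seq_len(2 * n - 2)
  data.frame(len = (height[parent[child]] - height[child]) / t,
             tip = I(tipsets[child]),
             is_tip = child <= n)
}

# closed-form expected heterozygous-site count per sexual sample under the
# thinning selfing model (used by calibration tests)
expected_sexual_het <- function(params) {
  ret <- retention_probs(params)$sex
  f <- params$annotation_fractions
  base <- (1 - params$selfing_F) * params$mu *
    sum(f * ret) * params$genome_length
  if (params$origin_mode == "within")
    base <- base + params$d_poly * sum(f * ret) * params$genome_length
  base
}
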