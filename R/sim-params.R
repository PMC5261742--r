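#' Parameters of the synthetic cohort generator
#'
#' Bundles and validates the generating parameters for [simulate_cohort()].
#' Defaults describe the stated world the analysis assumes: eight sympatric
#' sexual/apomict pairs, highly selfing sexuals (F_IS = 0.75), apomicts that
#' are non-recombining hybrids between a conspecific haplotype and a diverged
#' sister-species haplotype, and rho-fold relaxed retention of constrained-site
#' mutations in apomicts.
#'
#' @param genome_length Genome length in bp (single chromosome). Must be at
#'   least 10 x the 20 kb filter window so the window filter is exercisable.
#' @param n_pops Number of sympatric population pairs (default 8).
#' @param annotation_fractions Named proportions over the categories
#'   `0fold, 4fold, CNS, CCS, other`, summing to 1. Defaults roughly mirror a
#'   Brassicaceae-like genome: most of the genome unconstrained, coding sites
#'   split ~3:1 between 0-fold and 4-fold, plus conserved non-coding and
#'   conserved coding blocks.
#' @param mu Expected derived mutations per site accumulated along one lineage
#'   lifetime (root of the cohort to the present), before constrained-site
#'   thinning. Default 0.01, the per-terminal-branch mutation density scale
#'   seen in resequencing contrasts of this kind.
#' @param hybrid_divergence Substitutions/site separating the conspecific and
#'   sister-species founder haplotypes of a hybrid apomict (default 0.02).
#'   Split evenly between the two species stems.
#' @param selfing_F Inbreeding coefficient of sexual lineages in `[0,1]`
#'   (default 0.75): each sexual-lineage mutation is homozygous with
#'   probability `selfing_F`, heterozygous otherwise.
#' @param relax_factor_rho Multiplier (>= 0; 1 = equal selection) on the
#'   retention probability of constrained-site mutations in apomicts.
#' @param retain_constrained_sex Probability a constrained-site mutation
#'   survives purifying selection in a sexual lineage (default 0.2).
#' @param n_hybrid_origins Number of independent hybridization events shared
#'   among the apomicts (default 2: one origin for all but the last
#'   population, which gets its own, mirroring one divergent northern lineage).
#' @param origin_time Fraction of the lineage lifetime predating the apomictic
#'   origin (default 0.1: apomixis is old relative to the sampled lineages, so
#'   most mutation accumulation is post-origin).
#' @param origin_mode `"hybrid"` (default) or `"within"` for apomicts founded
#'   from within the sexual species (no sister-species haplotype).
#' @param d_poly Deep ancestral polymorphism rate used only by
#'   `origin_mode = "within"`: heterozygous sites of the sexual whose derived
#'   lineage is shared with the apomict founder (default 0.02).
#' @param block_bp,n_blocks Length and number of phased haplotype blocks
#'   emitted per apomict (defaults 2000 bp x 20, evenly spaced).
#' @param annotation_block_bp Length of the contiguous category runs used to
#'   lay down the annotation (default 200 bp), so window statistics see
#'   realistic clustering.
#' @param seed Integer seed; identical parameters and seed give byte-identical
#'   cohorts.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(genome_length = 1e6,
                       n_pops = 8,
                       annotation_fractions = c("0fold" = 0.12, "4fold" = 0.04,
                                                "CNS" = 0.06, "CCS" = 0.04,
                                                "other" = 0.74),
                       mu = 0.01,
                       hybrid_divergence = 0.02,
                       selfing_F = 0.75,
                       relax_factor_rho = 3,
                       retain_constrained_sex = 0.2,
                       n_hybrid_origins = 2,
                       origin_time = 0.1,
                       origin_mode = c("hybrid", "within"),
                       d_poly = 0.02,
                       block_bp = 2000,
                       n_blocks = 20,
                       annotation_block_bp = 200,
                       seed = 1) {
  origin_mode <- match.arg(origin_mode)
  if (!all(CATEGORIES %in% names(annotation_fractions)))
    stop("annotation_fractions must be named over: ",
         paste(CATEGORIES, collapse = ", "))
  annotation_fractions <- annotation_fractions[CATEGORIES]
  if (abs(sum(annotation_fractions) - 1) > 1e-9)
    stop("annotation_fractions must sum to 1")
  if (any(annotation_fractions < 0)) stop("annotation_fractions must be >= 0")
  if (selfing_F < 0 || selfing_F > 1) stop("selfing_F must be in [0,1]")
  if (relax_factor_rho < 0) stop("relax_factor_rho must be >= 0")
  if (retain_constrained_sex < 0 || retain_constrained_sex > 1)
    stop("retain_constrained_sex must be in [0,1]")
  if (genome_length < 10 * 20000)
    stop("genome_length must be >= 10 x the 20 kb filter window (200000 bp)")
  if (n_pops < 1) stop("n_pops must be >= 1")
  if (n_hybrid_origins < 1 || n_hybrid_origins > n_pops)
    stop("n_hybrid_origins must be between 1 and n_pops")
  if (origin_time <= 0 || origin_time >= 1)
    stop("origin_time must be in (0,1)")
  if (mu < 0 || hybrid_divergence < 0 || d_poly < 0)
    stop("rates must be >= 0")
  if (block_bp < 1 || n_blocks < 1 || n_blocks * block_bp > genome_length)
    stop("phased blocks do not fit in the genome")
  if (annotation_block_bp < 1 || annotation_block_bp > genome_length)
    stop("genome too short for requested annotation blocks")
  structure(list(
    genome_length = as.integer(genome_length), n_pops = as.integer(n_pops),
    annotation_fractions = annotation_fractions, mu = mu,
    hybrid_divergence = hybrid_divergence, selfing_F = selfing_F,
    relax_factor_rho = relax_factor_rho,
    retain_constrained_sex = retain_constrained_sex,
    n_hybrid_origins = as.integer(n_hybrid_origins),
    origin_time = origin_time, origin_mode = origin_mode, d_poly = d_poly,
    block_bp = as.integer(block_bp), n_blocks = as.integer(n_blocks),
    annotation_block_bp = as.integer(annotation_block_bp),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params:", x$genome_length, "bp,", x$n_pops, "population pairs,",
      x$origin_mode, "origin\n")
  cat(sprintf("  mu=%g, divergence=%g, F=%g, rho=%g, retain_sex=%g, origins=%d, seed=%d\n",
              x$mu, x$hybrid_divergence, x$selfing_F, x$relax_factor_rho,
              x$retain_constrained_sex, x$n_hybrid_origins, x$seed))
  invisible(x)
}

# per-category retention probabilities for the two selection regimes
retention_probs <- function(params) {
  r_sex <- setNames(rep(1, length(CATEGORIES)), CATEGORIES)
  r_sex[CONSTRAINED_CATEGORIES] <- params$retain_constrained_sex
  r_apo <- r_sex
  r_apo[CONSTRAINED_CATEGORIES] <-
    pmin(1, params$relax_factor_rho * params$retain_constrained_sex)
  list(sex = r_sex, apo = r_apo)
}
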