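#' Site annotation: constraint categories and ancestral alleles
#'
#' Couples a set of non-overlapping genomic intervals carrying constraint
#' categories (0-fold, 4-fold, CNS, CCS, other; BED convention, 0-based
#' half-open) with a reference sequence supplying the ancestral (outgroup)
#' allele at every position. Positions not covered by any interval fall in
#' category `"other"`.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `category` (one of [annotation_categories()]).
#' @param reference named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences; the base at each position is taken as ancestral.
#' @return An object of class `site_annotation`.
#' @export
site_annotation <- function(intervals, reference) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end", "category") %in% names(intervals)))
  bad <- setdiff(unique(intervals$category), CATEGORIES)
  if (length(bad) > 0)
    stop("malformed annotation category: ", paste(bad, collapse = ", "))
  if (methods::is(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference), names(reference))
  stopifnot(is.character(reference), !is.null(names(reference)))
  new_site_annotation(intervals, reference,
                      lapply(reference, function(s)
                        strsplit(s, "", fixed = TRUE)[[1]]))
}

# internal constructor; `chars` are the pre-split per-chromosome base vectors
new_site_annotation <- function(intervals, reference, chars) {
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  # split per chromosome for O(log n) interval lookup
  by_chrom <- split(intervals[c("start", "end", "category")], intervals$chrom)
  for (ch in names(by_chrom)) {
    iv <- by_chrom[[ch]]
    if (any(iv$start[-1] < iv$end[-nrow(iv)]))
      stop("overlapping annotation intervals on ", ch)
  }
  structure(list(
    intervals = intervals,
    by_chrom  = by_chrom,
    sequence  = reference,
    chars     = chars,
    chrom_lengths = vapply(reference, nchar, integer(1))
  ), class = "site_annotation")
}

#' @export
print.site_annotation <- function(x, ...) {
  cat("site_annotation:", length(x$sequence), "chromosome(s),",
      sum(x$chrom_lengths), "bp,", nrow(x$intervals), "intervals\n")
  tab <- tapply(x$intervals$end - x$intervals$start, x$intervals$category, sum)
  print(tab)
  invisible(x)
}

#' Look up the constraint category of genomic positions
#'
#' @param ann A [site_annotation()].
#' @param chrom,pos Equal-length vectors of chromosome names and 1-based
#'   positions.
#' @return Character vector of categories (`"other"` where uncovered).
#' @export
ann_category <- function(ann, chrom, pos) {
  stopifnot(inherits(ann, "site_annotation"), length(chrom) == length(pos))
  out <- rep("other", length(pos))
  for (ch in unique(chrom)) {
    iv <- ann$by_chrom[[ch]]
    if (is.null(iv)) next
    sel <- which(chrom == ch)
    p0 <- pos[sel] - 1L                      # to 0-based
    idx <- findInterval(p0, iv$start)
    hit <- idx > 0 & p0 < iv$end[pmax(idx, 1L)]
    out[sel[hit]] <- iv$category[idx[hit]]
  }
  out
}

#' Look up the ancestral (reference/outgroup) allele at genomic positions
#'
#' @inheritParams ann_category
#' @return Character vector of bases (`NA` outside the reference).
#' @export
ann_ancestral <- function(ann, chrom, pos) {
  stopifnot(inherits(ann, "site_annotation"), length(chrom) == length(pos))
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    chars <- ann$chars[[ch]]
    if (is.null(chars)) next
    sel <- which(chrom == ch)
    ok <- pos[sel] >= 1L & pos[sel] <= length(chars)
    out[sel[ok]] <- chars[pos[sel[ok]]]
  }
  out
}

#' Multi-sample table of biallelic SNP genotypes
#'
#' The substrate of all diversity statistics: a site list (chromosome, 1-based
#' position, REF/ALT alleles, site quality) plus a sites-by-samples matrix of
#' diploid genotype calls coded 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing, and a matching matrix of genotype
#' qualities.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`.
#' @param geno integer matrix (sites x samples) with sample column names.
#' @param gq numeric matrix of genotype qualities, same shape as `geno`
#'   (defaults to all `Inf`, i.e. never filtered).
#' @param chrom_lengths optional named integer vector of chromosome lengths
#'   (needed by the window filter to size trailing windows).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(sites, geno, gq = NULL, chrom_lengths = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "qual") %in% names(sites)))
  geno <- as.matrix(geno)
  if (nrow(sites) != nrow(geno))
    stop("sites and geno row counts differ")
  if (is.null(colnames(geno))) stop("geno must have sample column names")
  if (is.null(gq)) gq <- matrix(Inf, nrow(geno), ncol(geno),
                                dimnames = dimnames(geno))
  stopifnot(identical(dim(gq), dim(geno)))
  ok <- !is.na(geno)
  if (any(!(geno[ok] %in% 0:2))) stop("genotype codes must be 0, 1, 2 or NA")
  # strictly increasing positions within chromosome
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  geno <- geno[o, , drop = FALSE]
  gq <- gq[o, , drop = FALSE]
  dup <- duplicated(sites[c("chrom", "pos")])
  if (any(dup)) stop("duplicated site positions")
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno, gq = gq,
                 samples = colnames(geno),
                 chrom_lengths = chrom_lengths,
                 derived_is_alt = NULL,   # set by polarize_derived()
                 windows = NULL,          # retained windows, set by filter_sites()
                 log = character(0)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  if (!is.null(x$derived_is_alt)) cat("  polarized (derived alleles tagged)\n")
  if (!is.null(x$windows))
    cat("  window-filtered:", nrow(x$windows), "windows retained\n")
  for (l in x$log) cat("  ", l, "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(nrow(x$sites), length(x$samples))

n_sites <- function(table) nrow(table$sites)

tab_log <- function(table, ...) {
  table$log <- c(table$log, paste0(...))
  table
}

# sites polymorphic among the (non-missing) calls of the whole cohort:
# both alleles observed, counting a heterozygote as carrying both
is_polymorphic <- function(geno) {
  has_alt <- rowSums(geno > 0, na.rm = TRUE) > 0
  has_ref <- rowSums(geno < 2, na.rm = TRUE) > 0
  has_alt & has_ref
}
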