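#' Random pseudo-haplotypes of a diploid sample over a region
#'
#' Builds two haploid sequences for a (recombining, unphaseable) sample by
#' starting from the reference sequence, applying homozygous alternate calls
#' to both outputs, and randomly assigning the two alleles of each
#' heterozygous site to one output each (seeded uniform draw). Positions with
#' a missing genotype are emitted as `N` in both outputs; the per-site allele
#' multiset is always preserved.
#'
#' @param table A [genotype_table()].
#' @param reference Named character vector (or `DNAStringSet`) of chromosome
#'   sequences in the VCF coordinate system.
#' @param sample Sample name.
#' @param region list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return list with `hap1`, `hap2` (character strings of length
#'   `end - start`), and the `region`.
#' @export
make_pseudo_haplotypes <- function(table, reference, sample, region, seed = 1) {
  stopifnot(sample %in% table$samples)
  if (methods::is(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference), names(reference))
  ref_seq <- reference[[region$chrom]]
  if (is.null(ref_seq) || nchar(ref_seq) < region$end)
    stop("reference does not span the region")
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  h1 <- h2 <- strsplit(substr(ref_seq, region$start + 1L, region$end),
                       "", fixed = TRUE)[[1]]
  sel <- which(table$sites$chrom == region$chrom &
               table$sites$pos > region$start & table$sites$pos <= region$end)
  g <- table$geno[sel, sample]
  off <- table$sites$pos[sel] - region$start
  alt <- table$sites$alt[sel]
  ref <- table$sites$ref[sel]
  h1[off[!is.na(g) & g == 2L]] <- alt[!is.na(g) & g == 2L]
  h2[off[!is.na(g) & g == 2L]] <- alt[!is.na(g) & g == 2L]
  het <- which(!is.na(g) & g == 1L)
  flip <- runif(length(het)) < 0.5     # which output gets the ALT allele
  h1[off[het]] <- ifelse(flip, alt[het], ref[het])
  h2[off[het]] <- ifelse(flip, ref[het], alt[het])
  miss <- is.na(g)
  h1[off[miss]] <- "N"
  h2[off[miss]] <- "N"
  list(hap1 = paste(h1, collapse = ""), hap2 = paste(h2, collapse = ""),
       region = list(chrom = region$chrom, start = region$start,
                     end = region$end))
}

#' Assemble a five-taxon alignment for one region
#'
#' Stacks the two phased apomict haplotypes (A1, A2), the two sexual
#' pseudo-haplotypes (S1, S2) and the outgroup reference (OUT) over one
#' region, keeping only columns in which all five sequences have a called base
#' (A/C/G/T), and attaches the per-column constraint category.
#'
#' @param block One row of a phased-block data.frame (`chrom`, `start`, `end`,
#'   `hap1`, `hap2`).
#' @param pseudo A [make_pseudo_haplotypes()] result over the same region.
#' @param outgroup Named character vector (or `DNAStringSet`) with the
#'   outgroup sequence for `block$chrom`.
#' @param ann A [site_annotation()].
#' @return list of class `tax5_alignment`: `seqs` (5 x L character matrix,
#'   rows A1, A2, S1, S2, OUT), `pos` (1-based genomic position per column),
#'   `category` (per column), `region`; or `NULL` (with a message) if no
#'   usable column remains.
#' @export
assemble_alignment <- function(block, pseudo, outgroup, ann) {
  if (methods::is(outgroup, "DNAStringSet"))
    outgroup <- setNames(as.character(outgroup), names(outgroup))
  stopifnot(block$end - block$start ==  nchar(block$hap1),
            identical(pseudo$region$start, block$start) ||
              pseudo$region$start == block$start)
  width <- block$end - block$start
  out_seq <- substr(outgroup[[block$chrom]], block$start + 1L, block$end)
  seqs <- rbind(
    A1 = strsplit(block$hap1, "", fixed = TRUE)[[1]],
    A2 = strsplit(block$hap2, "", fixed = TRUE)[[1]],
    S1 = strsplit(pseudo$hap1, "", fixed = TRUE)[[1]],
    S2 = strsplit(pseudo$hap2, "", fixed = TRUE)[[1]],
    OUT = strsplit(out_seq, "", fixed = TRUE)[[1]])
  usable <- colSums(matrix(seqs %in% BASES, nrow = 5)) == 5L
  if (!any(usable)) {
    message("assemble_alignment: no usable columns in ", block$chrom, ":",
            block$start, "-", block$end, "; region skipped")
    return(NULL)
  }
  pos <- block$start + which(usable)
  structure(list(
    seqs = seqs[, usable, drop = FALSE],
    pos = pos,
    category = ann_category(ann, rep(block$chrom, length(pos)), pos),
    region = list(chrom = block$chrom, start = block$start, end = block$end)
  ), class = "tax5_alignment")
}

#' @export
print.tax5_alignment <- function(x, ...) {
  cat(sprintf("tax5_alignment %s:%d-%d, %d columns (%d variant)\n",
              x$region$chrom, x$region$start, x$region$end, ncol(x$seqs),
              sum(apply(x$seqs, 2, function(cc) length(unique(cc))) > 1)))
  invisible(x)
}
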