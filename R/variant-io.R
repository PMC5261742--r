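#' Read the standard input file set
#'
#' Reads a multi-sample VCF, a 4-column category BED, a reference/outgroup
#' FASTA and a sample sheet into the in-memory containers used by the rest of
#' the pipeline. Non-SNP and multiallelic VCF records are dropped with a logged
#' count. BED categories (0-based half-open intervals) are mapped onto 1-based
#' site positions; the reference base at every position is recorded as the
#' ancestral allele.
#'
#' @param vcf,bed,fasta,samples Paths to the four inputs. The sample sheet is a
#'   tab-separated file with columns `population`, `sexual`, `apomict`.
#' @return list with elements `table` ([genotype_table()]), `ann`
#'   ([site_annotation()]) and `samples` (data.frame).
#' @export
read_inputs <- function(vcf, bed, fasta, samples) {
  for (f in c(vcf, bed, fasta, samples))
    if (!file.exists(f)) stop("input file not found: ", f)
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ann <- site_annotation(read_bed(bed), ref)
  table <- read_vcf_table(vcf, chrom_lengths = ann$chrom_lengths)
  sheet <- read.delim(samples, stringsAsFactors = FALSE)
  need <- c("population", "sexual", "apomict")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(c(sheet$sexual, sheet$apomict), table$samples)
  if (length(missing) > 0)
    stop("sample sheet sample(s) absent from VCF: ",
         paste(missing, collapse = ", "))
  list(table = table, ann = ann, samples = sheet)
}

read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # back to 0-based
             end = GenomicRanges::end(gr),
             category = gr$name,
             stringsAsFactors = FALSE)
}

write_bed <- function(intervals, path) {
  df <- intervals[order(intervals$chrom, intervals$start), ]
  utils::write.table(df[c("chrom", "start", "end", "category")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

read_vcf_table <- function(path, chrom_lengths = NULL) {
  v <- VariantAnnotation::readVcf(path, genome = "cohort")
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  snp <- n_alt == 1 & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1 &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  gt <- VariantAnnotation::geno(v)$GT[snp, , drop = FALSE]
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  geno[gt %in% c("0/0", "0|0")] <- 0L
  geno[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt %in% c("1/1", "1|1")] <- 2L
  gq <- VariantAnnotation::geno(v)$GQ
  gq <- if (is.null(gq)) matrix(Inf, nrow(gt), ncol(gt), dimnames = dimnames(gt))
        else {
          m <- matrix(as.numeric(gq[snp, , drop = FALSE]), nrow(gt), ncol(gt),
                      dimnames = dimnames(gt))
          m[is.na(m)] <- Inf
          m
        }
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[snp],
    pos = GenomicRanges::start(rr)[snp],
    ref = ref[snp], alt = alt1[snp],
    qual = as.numeric(rr$QUAL)[snp],
    stringsAsFactors = FALSE)
  tab <- genotype_table(sites, geno, gq, chrom_lengths = chrom_lengths)
  tab_log(tab, "read_inputs: dropped ", n_drop, " non-SNP/multiallelic records")
}

#' Write a genotype table as a multi-sample VCF 4.2 file
#'
#' @param table A [genotype_table()].
#' @param path Output path.
#' @param contigs optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path, contigs = table$chrom_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=apomacc",
               if (!is.null(contigs))
                 sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                         as.integer(contigs)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", table$samples), collapse = "\t")),
             con)
  if (n_sites(table) > 0) {
    gt_str <- matrix("./.", nrow(table$geno), ncol(table$geno))
    gt_str[table$geno == 0L] <- "0/0"
    gt_str[table$geno == 1L] <- "0/1"
    gt_str[table$geno == 2L] <- "1/1"
    gq <- table$gq
    gq_str <- ifelse(is.na(table$geno), ".",
                     as.character(as.integer(pmin(gq, 999))))
    cells <- matrix(paste(gt_str, gq_str, sep = ":"), nrow(gt_str))
    body <- paste(table$sites$chrom, table$sites$pos, ".", table$sites$ref,
                  table$sites$alt, format(table$sites$qual, trim = TRUE),
                  "PASS", ".", "GT:GQ",
                  apply(cells, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Apply site, genotype and window quality filters
#'
#' Reproduces the standard SNP filtering cascade: sites below a site-quality
#' threshold are removed; genotype calls below a genotype-quality threshold are
#' set to missing; non-overlapping windows (0-based half-open, anchored at
#' position 0 of each chromosome) in which fewer than `min_callable_frac` of
#' the reference bases carry a passing call in at least one sample are removed
#' entirely; finally only sites still polymorphic among the retained samples
#' are kept. The filter is idempotent.
#'
#' @param table A [genotype_table()].
#' @param site_qual_min Minimum site QUAL (default 15).
#' @param gt_qual_min Minimum genotype GQ (default 40).
#' @param window_bp Window size in bp (default 20000).
#' @param min_callable_frac Minimum fraction of window bases with a passing
#'   call in >= 1 sample (default 0.30). Use 0 for variant-only input in which
#'   monomorphic callable sites are not represented.
#' @return The filtered `genotype_table`; its `windows` element records the
#'   retained windows and the `log` element the per-stage drop counts. An
#'   empty result raises a warning of class `apomacc_empty_result`.
#' @export
filter_sites <- function(table, site_qual_min = 15, gt_qual_min = 40,
                         window_bp = 20000, min_callable_frac = 0.30) {
  stopifnot(inherits(table, "genotype_table"),
            site_qual_min >= 0, gt_qual_min >= 0, window_bp > 0,
            min_callable_frac >= 0, min_callable_frac <= 1)
  n0 <- n_sites(table)
  keep <- !is.na(table$sites$qual) & table$sites$qual >= site_qual_min
  table <- subset_sites(table, keep)
  n_siteq <- n0 - n_sites(table)

  low_gq <- !is.na(table$geno) & table$gq < gt_qual_min
  n_gq <- sum(low_gq)
  table$geno[low_gq] <- NA_integer_

  # window filter: callable fraction over all reference bases in the window.
  # A previously filtered table carries its window callable counts; reusing
  # them (rather than recounting from the reduced site set, which no longer
  # holds the dropped monomorphic/low-quality sites) makes the filter
  # idempotent.
  win_id <- if (n_sites(table) == 0) character(0) else
    paste0(table$sites$chrom, ":", (table$sites$pos - 1L) %/% window_bp)
  stored <- table$windows
  reuse <- !is.null(stored) && (nrow(stored) == 0 ||
    all(stored$start %% window_bp == 0 & stored$end - stored$start <= window_bp))
  if (reuse) {
    n_callable <- setNames(stored$callable,
                           paste0(stored$chrom, ":", stored$start %/% window_bp))
  } else {
    callable <- rowSums(!is.na(table$geno)) > 0
    n_callable <- if (n_sites(table) == 0)
      setNames(numeric(0), character(0)) else tapply(callable, win_id, sum)
  }
  win_chrom <- sub(":.*$", "", names(n_callable))
  win_idx <- as.numeric(sub("^.*:", "", names(n_callable)))
  win_start <- win_idx * window_bp
  win_end <- win_start + window_bp
  if (!is.null(table$chrom_lengths))
    win_end <- pmin(win_end, table$chrom_lengths[win_chrom])
  frac <- as.numeric(n_callable) / (win_end - win_start)
  keep_win <- names(n_callable)[frac >= min_callable_frac]
  n_win_drop <- length(n_callable) - length(keep_win)
  table <- subset_sites(table, win_id %in% keep_win)
  win_id <- win_id[win_id %in% keep_win]
  o <- order(win_chrom, win_start)
  sel <- names(n_callable)[o] %in% keep_win
  table$windows <- data.frame(chrom = win_chrom[o], start = win_start[o],
                              end = win_end[o],
                              callable = as.numeric(n_callable)[o],
                              stringsAsFactors = FALSE)[sel, , drop = FALSE]
  rownames(table$windows) <- NULL

  poly <- is_polymorphic(table$geno)
  n_mono <- sum(!poly)
  table <- subset_sites(table, poly)

  table <- tab_log(table,
    sprintf(paste0("filter_sites: %d low-qual sites, %d low-GQ genotypes, ",
                   "%d windows (< %.0f%% callable), %d monomorphic sites removed; ",
                   "%d sites retained"),
            n_siteq, n_gq, n_win_drop, 100 * min_callable_frac, n_mono,
            n_sites(table)))
  if (n_sites(table) == 0)
    warning(structure(class = c("apomacc_empty_result", "warning", "condition"),
                      list(message = "no sites retained after filtering",
                           call = sys.call())))
  table
}

subset_sites <- function(table, keep) {
  table$sites <- table$sites[keep, , drop = FALSE]
  rownames(table$sites) <- NULL
  table$geno <- table$geno[keep, , drop = FALSE]
  table$gq <- table$gq[keep, , drop = FALSE]
  if (!is.null(table$derived_is_alt))
    table$derived_is_alt <- table$derived_is_alt[keep]
  table
}

#' Polarize alleles into ancestral and derived states
#'
#' Tags each site with which of REF/ALT is the derived allele: the allele
#' absent from the outgroup/ancestral reference. Sites whose ancestral allele
#' matches neither REF nor ALT, or is unavailable, are excluded with a logged
#' count.
#'
#' @param table A [genotype_table()].
#' @param ann A [site_annotation()] supplying ancestral alleles.
#' @return The table restricted to polarizable sites, with `derived_is_alt`
#'   set (`TRUE` when ALT is derived).
#' @export
polarize_derived <- function(table, ann) {
  stopifnot(inherits(table, "genotype_table"), inherits(ann, "site_annotation"))
  anc <- ann_ancestral(ann, table$sites$chrom, table$sites$pos)
  is_alt <- ifelse(!is.na(anc) & anc == table$sites$ref, TRUE,
                   ifelse(!is.na(anc) & anc == table$sites$alt, FALSE, NA))
  n_drop <- sum(is.na(is_alt))
  table$derived_is_alt <- is_alt
  table <- subset_sites(table, !is.na(is_alt))
  tab_log(table, "polarize_derived: excluded ", n_drop,
          " unpolarizable sites; ", n_sites(table), " retained")
}

#' Per-sample missingness report
#'
#' @param table A [genotype_table()].
#' @return data.frame with per-sample counts of missing calls and percent NA,
#'   so users can verify missingness is consistent across samples.
#' @export
missingness_report <- function(table) {
  n_na <- colSums(is.na(table$geno))
  data.frame(sample = table$samples, n_missing = as.integer(n_na),
             pct_na = if (n_sites(table) > 0) 100 * n_na / n_sites(table) else 0,
             row.names = NULL)
}
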