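#' Write a simulated cohort to a directory of standard files
#'
#' Emits the file set consumed by [read_inputs()] plus the phased haplotype
#' blocks and the truth log: `cohort.vcf` (multi-sample VCF 4.2 with QUAL and
#' per-genotype GQ), `reference.fa`, `annotation.bed` (0-based half-open,
#' 4th column = category), `blocks.tsv` (chrom, start, end, two haploid
#' sequences per apomict block), `samples.tsv` and `truth.json`. Files
#' round-trip losslessly through the package readers.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(vcf = file.path(out_dir, "cohort.vcf"),
             fasta = file.path(out_dir, "reference.fa"),
             bed = file.path(out_dir, "annotation.bed"),
             blocks = file.path(out_dir, "blocks.tsv"),
             samples = file.path(out_dir, "samples.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_vcf(cohort$table, paths["vcf"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(cohort$reference), paths["fasta"])
  write_bed(cohort$ann$intervals, paths["bed"])
  utils::write.table(cohort$blocks, paths["blocks"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(paths)
}

#' Read phased apomict haplotype blocks
#'
#' @param path Tab-separated file with columns `sample`, `chrom`, `start`,
#'   `end` (0-based half-open) and the two haploid sequences `hap1`, `hap2`.
#' @return data.frame of blocks.
#' @export
read_phased_blocks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "hap1", "hap2")
  if (!all(need %in% names(df)))
    stop("phased block file must have columns: ", paste(need, collapse = ", "))
  bad <- nchar(df$hap1) != df$end - df$start | nchar(df$hap2) != df$end - df$start
  if (any(bad)) stop("haplotype sequence length does not match block span")
  df
}

#' Read a written cohort directory back into memory
#'
#' @param dir Directory written by [write_cohort()].
#' @return list with `table`, `ann`, `samples`, `blocks`, `truth`.
#' @export
read_cohort <- function(dir) {
  inp <- read_inputs(file.path(dir, "cohort.vcf"),
                     file.path(dir, "annotation.bed"),
                     file.path(dir, "reference.fa"),
                     file.path(dir, "samples.tsv"))
  inp$blocks <- read_phased_blocks(file.path(dir, "blocks.tsv"))
  inp$truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE)
  inp
}
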