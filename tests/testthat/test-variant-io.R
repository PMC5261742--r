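toy_dir <- system.file("extdata", package = "apomacc")
toy <- list(vcf = file.path(toy_dir, "toy_cohort.vcf"),
            bed = file.path(toy_dir, "toy_annotation.bed"),
            fasta = file.path(toy_dir, "toy_reference.fa"),
            samples = file.path(toy_dir, "toy_samples.tsv"))

test_that("read_inputs drops non-SNP records with a logged count", {
  inp <- read_inputs(toy$vcf, toy$bed, toy$fasta, toy$samples)
  # the fixture carries 5 multiallelic and 2 indel records
  expect_equal(n_sites(inp$table), 385L)
  expect_match(inp$table$log[1], "dropped 7 non-SNP/multiallelic")
  expect_s3_class(inp$ann, "site_annotation")
  expect_equal(inp$samples$population, c("popA", "popB"))
})

test_that("read_inputs validates the sample sheet against the VCF", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(population = "popA", sexual = "nope",
                         apomict = "apoA"),
              bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_inputs(toy$vcf, toy$bed, toy$fasta, bad),
               "absent from VCF")
})

test_that("BED intervals follow the 0-based half-open convention", {
  fx <- tiny_fixture(cbind(a = c(1L, 1L), b = c(0L, 2L)), pos = c(5L, 15L),
                     chrom_len = 40L,
                     intervals = data.frame(chrom = "chr1", start = 10L,
                                            end = 20L, category = "CNS"))
  # interval [10, 20) covers 1-based positions 11..20
  expect_equal(ann_category(fx$ann, rep("chr1", 4), c(10L, 11L, 20L, 21L)),
               c("other", "CNS", "CNS", "other"))
  # and category_bases counts exactly its width
  expect_equal(unname(category_bases(fx$ann)[["CNS"]]), 10)
})

test_that("filter cascade matches hand enumeration on the toy fixture", {
  inp <- read_inputs(toy$vcf, toy$bed, toy$fasta, toy$samples)
  f <- filter_sites(inp$table)  # defaults 15 / 40 / 20 kb / 0.30
  # independent enumeration from the raw VCF text
  lines <- grep("^#", readLines(toy$vcf), value = TRUE, invert = TRUE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  snp <- vapply(fields, function(x) nchar(x[4]) == 1 && nchar(x[5]) == 1, TRUE)
  fields <- fields[snp]
  qual_ok <- vapply(fields, function(x) as.numeric(x[6]) >= 15, TRUE)
  fields <- fields[qual_ok]
  gt <- t(vapply(fields, function(x) {
    cell <- strsplit(x[10:13], ":", fixed = TRUE)
    vapply(cell, function(cc)
      if (as.integer(cc[2]) < 40) NA_character_ else cc[1], "")
  }, character(4)))
  chrom <- vapply(fields, `[[`, "", 1)
  callable <- rowSums(!is.na(gt)) > 0
  chrlen <- c(chrA = 300, chrB = 400, chrC = 500)
  keep_win <- names(which(tapply(callable, chrom, sum) / chrlen >= 0.30))
  has_alt <- rowSums(gt == "0/1" | gt == "1/1", na.rm = TRUE) > 0
  has_ref <- rowSums(gt == "0/1" | gt == "0/0", na.rm = TRUE) > 0
  expected <- sum(chrom %in% keep_win & callable & has_alt & has_ref)
  expect_equal(n_sites(f), expected)
  expect_equal(n_sites(f), 270L)          # frozen hand count
  expect_equal(nrow(f$windows), 2L)       # chrB's window fails 30%
  expect_false("chrB" %in% f$windows$chrom)
  # a site with quality 14.9 is removed under the threshold of 15
  expect_false(any(f$sites$qual < 15))
})

test_that("no-op thresholds reduce to the polymorphism filter", {
  inp <- read_inputs(toy$vcf, toy$bed, toy$fasta, toy$samples)
  f0 <- filter_sites(inp$table, site_qual_min = 0, gt_qual_min = 0,
                     min_callable_frac = 0)
  poly <- apomacc:::is_polymorphic(inp$table$geno)
  expect_equal(n_sites(f0), sum(poly))
  expect_identical(f0$sites$pos, inp$table$sites$pos[poly])
})

test_that("filtering is idempotent and monotone in site quality", {
  set.seed(42)
  for (rep in 1:5) {
    g <- matrix(sample(c(0:2, NA), 120, replace = TRUE), 30)
    fx <- tiny_fixture(g, pos = sort(sample(1:2000, 30)), chrom_len = 2100L,
                       qual = round(runif(30, 5, 60), 1), seed = rep)
    fx$table$gq <- matrix(sample(20:99, 120, replace = TRUE), 30,
                          dimnames = dimnames(fx$table$gq))
    f1 <- suppressWarnings(filter_sites(fx$table, window_bp = 500,
                                        min_callable_frac = 0.01))
    f2 <- suppressWarnings(filter_sites(f1, window_bp = 500,
                                        min_callable_frac = 0.01))
    expect_identical(f1$sites, f2$sites)
    expect_identical(f1$geno, f2$geno)
    # raising the site-quality threshold never increases retained sites
    counts <- vapply(c(0, 15, 30, 45, 60), function(q)
      n_sites(suppressWarnings(filter_sites(fx$table, site_qual_min = q,
                                            min_callable_frac = 0))), 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("an empty filter result warns with a dedicated condition class", {
  fx <- tiny_fixture(cbind(a = 1L, b = 0L), qual = 5)
  expect_warning(filter_sites(fx$table), class = "apomacc_empty_result")
})

test_that("samples are never dropped and missingness is reported", {
  inp <- read_inputs(toy$vcf, toy$bed, toy$fasta, toy$samples)
  f <- filter_sites(inp$table)
  expect_identical(f$samples, inp$table$samples)
  mr <- missingness_report(f)
  expect_equal(mr$sample, f$samples)
  expect_true(all(mr$n_missing >= 0))
})

test_that("polarization tags the non-ancestral allele and drops the rest", {
  fx <- tiny_fixture(cbind(a = c(1L, 1L, 1L), b = c(2L, 0L, 0L)),
                     pos = c(10L, 20L, 30L),
                     ref = c("A", "A", "C"), alt = c("G", "G", "T"))
  # make position 20's true ancestral base C: matches neither REF nor ALT
  chars <- strsplit(fx$reference, "")[[1]]
  chars[20] <- "C"
  ann <- site_annotation(fx$ann$intervals,
                         setNames(paste(chars, collapse = ""), "chr1"))
  pz <- polarize_derived(fx$table, ann)
  expect_equal(n_sites(pz), 2L)
  expect_equal(pz$sites$pos, c(10L, 30L))
  expect_identical(pz$derived_is_alt, c(TRUE, TRUE))
  expect_match(pz$log[length(pz$log)], "excluded 1 unpolarizable")
  # fixture: 2 planted unpolarizable records survive the filters
  inp <- read_inputs(toy$vcf, toy$bed, toy$fasta, toy$samples)
  pz2 <- polarize_derived(filter_sites(inp$table), inp$ann)
  expect_equal(n_sites(pz2), 268L)
})

test_that("derived assignments agree with the simulator truth log", {
  co <- simulate_cohort(sim_params(genome_length = 2e5, seed = 11))
  tb <- polarize_derived(
    suppressWarnings(filter_sites(co$table, min_callable_frac = 0)), co$ann)
  # the reference is ancestral by construction: ALT is derived at every site
  expect_true(all(tb$derived_is_alt))
  m <- co$truth$mutations[match(tb$sites$pos, co$truth$mutations$pos), ]
  expect_identical(tb$sites$alt, m$base)
})

test_that("filtered tables serialize back to VCF and re-read identically", {
  inp <- read_inputs(toy$vcf, toy$bed, toy$fasta, toy$samples)
  f <- filter_sites(inp$table)
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(f, out, contigs = c(chrA = 300L, chrB = 400L, chrC = 500L))
  back <- apomacc:::read_vcf_table(out)
  expect_identical(back$sites[c("chrom", "pos", "ref", "alt")],
                   f$sites[c("chrom", "pos", "ref", "alt")])
  expect_identical(unname(back$geno), unname(f$geno))
})
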