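test_that("VCF round trip preserves the dosage matrix and sample order", {
  set.seed(11)
  g <- random_geno(6, 40, miss = 0.1, chrom = c("LG01"))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, f)
  g2 <- read_vcf(f)
  expect_identical(unname(g2$dosage), unname(g$dosage))
  expect_identical(g2$samples, g$samples)
  expect_equal(g2$sites$pos, g$sites$pos)
  expect_equal(g2$sites$ref, g$sites$ref)
  # sample columns in the VCF header match the geno sample order
  hdr <- grep("^#CHROM", readLines(f), value = TRUE)
  expect_identical(utils::tail(strsplit(hdr, "\t")[[1]], 6), g$samples)
})

test_that("read_vcf decodes phased, unphased and missing genotypes", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "LG01\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/1\t1|1",
    "LG01\t200\t.\tG\tT\t.\tPASS\t.\tGT\t./.\t0|0",
    "LG01\t300\t.\tA\tC,T\t.\tPASS\t.\tGT\t1/2\t0/0"
  ), f)
  g <- read_vcf(f)
  expect_equal(unname(g$dosage[, 1]), c(1L, 2L))
  expect_true(is.na(g$dosage[1, 2]) && g$dosage[2, 2] == 0L)
  # triallelic record dropped and counted
  expect_equal(n_sites(g), 2L)
  expect_equal(attr(g, "n_multiallelic_dropped"), 1L)
})

test_that("malformed records fail with a line number", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta",
    "LG01\t100\t.\tA\tC\t.\tPASS\t.\tGT"
  ), f)
  expect_error(read_vcf(f), "line 3")
})

test_that("site filters apply the stated rules in order and report counts", {
  # sites: 1 = fine; 2 = 60% missing; 3 = low MAF; 4 = C/T transition
  d <- rbind(c(0L, NA, 0L, 1L),
             c(1L, NA, 0L, 1L),
             c(2L, NA, 0L, 1L),
             c(0L, 1L, 0L, 1L),
             c(1L, 2L, 1L, 1L))
  g <- make_geno(d, ref = c("A", "A", "A", "C"), alt = c("C", "C", "C", "T"))
  out <- filter_sites(g, max_site_missing = 0.5, maf = 0.15,
                      drop_transitions = TRUE)
  expect_equal(n_sites(out), 1L)
  rep <- filter_report(out)
  expect_equal(rep$removed[rep$rule == "site_missingness"], 1L)
  expect_equal(rep$removed[rep$rule == "maf"], 1L)
  expect_equal(rep$removed[rep$rule == "transitions"], 1L)
  # G/A pair is dropped in either orientation
  g2 <- make_geno(matrix(c(0L, 1L, 2L), 3), ref = "G", alt = "A")
  expect_equal(n_sites(filter_sites(g2, drop_transitions = TRUE)), 0L)
  expect_error(filter_sites(g, maf = 0.5), "MAF")
})

test_that("filters are idempotent", {
  set.seed(7)
  g <- random_geno(10, 60, miss = 0.25)
  once <- filter_sites(g, max_site_missing = 0.3, maf = 0.1)
  twice <- filter_sites(once, max_site_missing = 0.3, maf = 0.1)
  expect_identical(unname(twice$dosage), unname(once$dosage))
  expect_true(all(filter_report(twice)$removed == 0))
})

test_that("ld_prune removes one of a duplicated pair and matches brute force", {
  set.seed(3)
  n <- 60
  base <- rbinom(n, 2, 0.5)
  indep <- replicate(3, rbinom(n, 2, 0.5))
  # site 2 duplicates site 1 (r2 = 1); sites 3-5 independent
  d <- cbind(base, base, indep)
  g <- make_geno(d)
  pruned <- ld_prune(g, window_snps = 5, step_snps = 1, r2_max = 0.5)
  expect_equal(n_sites(pruned), 4L)
  expect_true(all((cor(pruned$dosage)^2)[upper.tri(diag(4))] <= 0.5,
                  na.rm = TRUE))
  # exhaustive all-pairs check on a crafted correlated pair (r2 ~ 0.9)
  noisy <- base
  flip <- sample(n, 3)
  noisy[flip] <- 2L - noisy[flip]
  d2 <- cbind(base, noisy, indep)
  expect_gt(cor(d2)[1, 2]^2, 0.5)
  g2 <- make_geno(d2)
  pruned2 <- ld_prune(g2, window_snps = 5, step_snps = 1, r2_max = 0.5)
  # brute force: exactly the pairs above threshold lose one member
  over <- which(cor(d2)^2 > 0.5 & upper.tri(diag(5)), arr.ind = TRUE)
  expect_equal(n_sites(pruned2), 5L - nrow(over))
  expect_true(all((cor(pruned2$dosage)^2)[upper.tri(diag(n_sites(pruned2)))]
                  <= 0.5))
})

test_that("ld_prune keeps independent sites and ignores sample order", {
  set.seed(5)
  g <- random_geno(40, 20)
  pruned <- ld_prune(g, window_snps = 10, step_snps = 2, r2_max = 0.9)
  expect_equal(n_sites(pruned), 20L)
  shuf <- g[sample(g$samples), ]
  expect_equal(sites(ld_prune(shuf, 10, 2, 0.5))$pos,
               sites(ld_prune(g, 10, 2, 0.5))$pos)
})

test_that("region exclusion follows BED half-open coordinates", {
  g <- make_geno(matrix(0:2, 3, 3), pos = c(100L, 101L, 250L))
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("LG01\t100\t200\tinv", f)   # 0-based half-open [100, 200)
  bed <- read_bed(f)
  expect_equal(bed$start, 101L)
  expect_equal(bed$end, 200L)
  kept <- exclude_regions(g, bed)
  expect_equal(sites(kept)$pos, c(100L, 250L))   # 1-based 101 excluded
  expect_equal(sites(restrict_to_regions(g, bed))$pos, 101L)
  # empty region set is the identity
  expect_identical(unname(exclude_regions(g, bed[0, ])$dosage),
                   unname(g$dosage))
  # unknown chromosome warns and is ignored
  expect_warning(out <- exclude_regions(g, tibble::tibble(
    chrom = "LG99", start = 1, end = 1e6)), "unknown")
  expect_equal(n_sites(out), 3L)
  # write_bed round-trips the 1-based convention
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(bed, f2)
  expect_equal(read_bed(f2), bed)
})
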