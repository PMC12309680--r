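# small helper configs -------------------------------------------------------
two_year_cfg <- function(n = 500, snps = 300, years = c(1900, 1910),
                         gens_per_year = 1, m = NULL, ...) {
  sim_config(
    n_migratory = n, n_coastal = n,
    year_start = years[1], year_end = years[2],
    generation_time_years = gens_per_year,
    n_neutral_snps = snps, n_chromosomes = 2,
    burn_in_generations = 0,
    migration = if (is.null(m)) {
      tibble::tibble(year_from = 0, year_to = 0, m_cm = 0, m_mc = 0)
    } else m,
    inversions = list(),
    sampling = data.frame(year = years, population = "migratory", n = 50),
    age_range = c(0L, 0L), missingness = NULL, ...
  )
}

test_that("configuration invariants are enforced", {
  expect_error(two_year_cfg(n = 20), "census")
  expect_error(sim_config(migration = tibble::tibble(
    year_from = 1900, year_to = 1910, m_cm = 1.5, m_mc = 0)), "migration")
  expect_error(sim_config(selection = data.frame(
    year_from = 1900, year_to = 1910, inversion = "inv_LG01",
    w_anc = 1, w_het = -1, w_der = 1)), "fitness")
  expect_error(sim_config(sampling = data.frame(
    year = 1700, population = "migratory", n = 5)), "sampling years")
  expect_error(sim_config(inversions = list(
    inversion_spec("bad", "LG01", 10, 20, tag_fidelity = 0.4))),
    "tag_fidelity")
})

test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- two_year_cfg(n = 100, snps = 80)
  s1 <- simulate_cohorts(cfg)
  s2 <- simulate_cohorts(cfg)
  expect_identical(s1$geno$dosage, s2$geno$dosage)
  expect_identical(s1$truth$ancestry, s2$truth$ancestry)
  cfg2 <- cfg; cfg2$seed <- 2L
  s3 <- simulate_cohorts(cfg2)
  expect_false(identical(s1$geno$dosage, s3$geno$dosage))
})

test_that("neutrality martingale: mean terminal frequency equals the start", {
  # many independent loci stand in for replicate runs of a single locus
  set.seed(42)
  cfg <- two_year_cfg(n = 200, snps = 4000, years = c(0, 20))
  sim <- simulate_cohorts(cfg)
  p0 <- sim$truth$freq_migratory[, 1]
  pt <- sim$truth$freq_migratory[, 21]
  expect_lt(abs(mean(pt - p0)), 0.01)
})

test_that("drift variance matches 1 - (1 - 1/2N)^t within 15%", {
  set.seed(43)
  cfg <- two_year_cfg(n = 200, snps = 5000, years = c(0, 20))
  sim <- simulate_cohorts(cfg)
  p0 <- sim$truth$freq_migratory[, 1]
  pt <- sim$truth$freq_migratory[, 21]
  expected <- p0 * (1 - p0) * (1 - (1 - 1 / (2 * 200))^20)
  ratio <- mean((pt - p0)^2) / mean(expected)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("karyotype genotype counts are consistent with random mating", {
  # neutral replicates: HWE chi-square non-significant in >= 90%
  reject <- vapply(1:40, function(r) {
    cfg <- sim_config(
      n_migratory = 300, n_coastal = 300, year_start = 0, year_end = 10,
      generation_time_years = 1, n_neutral_snps = 10, n_chromosomes = 1,
      chromosome_length_bp = 1e6, burn_in_generations = 0,
      migration = tibble::tibble(year_from = 0, year_to = 0, m_cm = 0, m_mc = 0),
      inversions = list(inversion_spec("inv", "LG01", 2e5, 6e5,
                                       n_block_snps = 5,
                                       init_freq_migratory = 0.5,
                                       init_freq_coastal = 0.5)),
      sampling = data.frame(year = 10, population = "migratory", n = 100),
      age_range = c(0L, 0L), missingness = NULL, seed = r
    )
    sim <- simulate_cohorts(cfg)
    counts <- table(factor(sim$truth$karyotypes$karyotype,
                           levels = c("ANCESTRAL", "HET", "DERIVED")))
    hwe_chisq(as.integer(counts))$p < 0.05
  }, logical(1))
  expect_lte(mean(reject), 0.10)
})

test_that("heterozygote advantage drives HET frequency up toward equilibrium", {
  het_at <- function(seed) {
    cfg <- sim_config(
      n_migratory = 2000, n_coastal = 2000, year_start = 0, year_end = 15,
      generation_time_years = 1, n_neutral_snps = 5, n_chromosomes = 1,
      chromosome_length_bp = 1e6, burn_in_generations = 0,
      migration = tibble::tibble(year_from = 0, year_to = 0, m_cm = 0, m_mc = 0),
      inversions = list(inversion_spec("inv", "LG01", 2e5, 6e5,
                                       n_block_snps = 5,
                                       init_freq_migratory = 0.15,
                                       init_freq_coastal = 0.15)),
      selection = data.frame(year_from = 0, year_to = 15, inversion = "inv",
                             w_anc = 1, w_het = 1.3, w_der = 1),
      sampling = data.frame(year = 15, population = "migratory", n = 10),
      age_range = c(0L, 0L), missingness = NULL, seed = seed
    )
    q <- simulate_cohorts(cfg)$truth$inversion_freq$freq_migratory
    2 * q * (1 - q)   # expected HET frequency per generation
  }
  het <- rowMeans(vapply(1:20, het_at, numeric(16)))
  # monotone-in-expectation rise toward the polymorphic equilibrium at 0.5
  expect_gt(het[16], het[1])
  expect_gt(mean(diff(het) > 0), 0.8)
  expect_lt(abs(het[16] - 0.5), 0.1)
})

test_that("perfect tagging makes fixed migratory samples homozygous DERIVED", {
  cfg <- sim_config(
    n_migratory = 100, n_coastal = 100, year_start = 1900, year_end = 1910,
    generation_time_years = 1, n_neutral_snps = 20, n_chromosomes = 1,
    chromosome_length_bp = 1e6, burn_in_generations = 0,
    migration = tibble::tibble(year_from = 0, year_to = 0, m_cm = 0, m_mc = 0),
    inversions = list(inversion_spec("inv", "LG01", 2e5, 6e5,
                                     n_block_snps = 30, tag_fidelity = 1,
                                     init_freq_migratory = 1,
                                     init_freq_coastal = 0)),
    sampling = data.frame(year = c(1910, 1910),
                          population = c("migratory", "coastal"), n = 20),
    age_range = c(0L, 0L), missingness = NULL
  )
  sim <- simulate_cohorts(cfg)
  block <- restrict_to_regions(sim$geno, inversion_regions(cfg))
  mig <- sim$samples$sample_id[sim$samples$ecotype == "migratory"]
  cst <- sim$samples$sample_id[sim$samples$ecotype == "coastal"]
  expect_true(all(block[mig, ]$dosage == 2L))
  expect_true(all(block[cst, ]$dosage == 0L))
})

test_that("a migration pulse shows up in newborn ancestry at the mixing rate", {
  anc <- unlist(lapply(1:30, function(r) {
    cfg <- two_year_cfg(
      n = 300, snps = 5, years = c(0, 5),
      m = tibble::tibble(year_from = 5, year_to = 5, m_cm = 0.15, m_mc = 0))
    cfg$seed <- r
    cfg$sampling <- tibble::as_tibble(
      data.frame(year = 5, population = "migratory", n = 40))
    cfg <- tempogen:::validate_sim_config(cfg)
    simulate_cohorts(cfg)$truth$ancestry$coastal_ancestry
  }))
  # each parent is coastal with probability 0.15 -> mean newborn ancestry 0.15
  expect_lt(abs(mean(anc) - 0.15), 0.015)
  expect_true(all(anc %in% c(0, 0.5, 1)))
})

test_that("inject_missingness hits the scheduled rates and is seed-stable", {
  set.seed(1)
  g <- random_geno(50, 200)
  meta <- tibble::tibble(sample_id = g$samples,
                         catch_year = rep(c(1907, 2011), each = 25))
  sched <- tibble::tibble(year_to = c(1999, Inf), miss_rate = c(0.2, 0),
                          error_rate = 0)
  out <- inject_missingness(g, meta, sched, seed = 9)
  out2 <- inject_missingness(g, meta, sched, seed = 9)
  expect_identical(out$dosage, out2$dosage)
  old <- meta$catch_year <= 1999
  n_old <- sum(is.na(out$dosage[old, ]))
  # binomial 99% band around 25 * 200 * 0.2 = 1000
  band <- qbinom(c(0.005, 0.995), 25 * 200, 0.2)
  expect_gte(n_old, band[1])
  expect_lte(n_old, band[2])
  expect_identical(out$dosage[!old, ], g$dosage[!old, ])
  # rate 0 keeps the matrix; rate 1 blanks it
  none <- inject_missingness(g, meta, tibble::tibble(
    year_to = Inf, miss_rate = 0, error_rate = 0), seed = 1)
  expect_identical(none$dosage, g$dosage)
  all_na <- inject_missingness(g, meta, tibble::tibble(
    year_to = Inf, miss_rate = 1, error_rate = 0), seed = 1)
  expect_true(all(is.na(all_na$dosage)))
})

test_that("genotyping errors move dosages to a different state", {
  set.seed(2)
  g <- make_geno(matrix(1L, 20, 50))
  meta <- tibble::tibble(sample_id = g$samples, catch_year = 1907)
  out <- inject_missingness(g, meta, tibble::tibble(
    year_to = Inf, miss_rate = 0, error_rate = 0.3), seed = 3)
  flipped <- out$dosage != 1L
  expect_gt(mean(flipped), 0.2)
  expect_true(all(out$dosage[flipped] %in% c(0L, 2L)))
})

test_that("write_sim_outputs round-trips through read_vcf and keeps order", {
  cfg <- two_year_cfg(n = 60, snps = 30)
  cfg$sampling <- tibble::as_tibble(
    data.frame(year = c(1900, 1910), population = "migratory", n = 5))
  cfg <- tempogen:::validate_sim_config(cfg)
  sim <- simulate_cohorts(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_outputs(sim, dir)
  g2 <- read_vcf(paths$vcf)
  expect_identical(unname(g2$dosage), unname(sim$geno$dosage))
  meta <- read_metadata(paths$meta)
  expect_identical(meta$sample_id, sim$samples$sample_id)
  expect_identical(g2$samples, meta$sample_id)
})
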