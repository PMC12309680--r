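test_that("Tajima's D matches the constant-by-constant oracle", {
  # n = 10 alleles (5 diploids), S = 5, all singletons -> negative D
  d <- rbind(matrix(c(1L, 0L, 0L, 0L, 0L), 5, 5, byrow = FALSE) * 0L)
  d <- matrix(0L, 5, 5)
  for (j in 1:5) d[j, j] <- 1L
  g <- make_geno(d, pos = 1:5 * 10L)
  win <- tajimas_d_windows(g, g$samples, window_bp = 1000, step_bp = 1000)
  expect_equal(nrow(win), 1L)
  expect_lt(win$d, 0)
  want <- oracle_tajima_d(rep(1 / 10, 5), rep(10, 5))
  expect_equal(win$d, want, tolerance = 1e-9)
  # balanced two-haplotype block (inversion-like) at frequency 0.5 -> D > 0
  blk <- make_geno(rbind(matrix(2L, 2, 8), matrix(1L, 4, 8),
                         matrix(0L, 2, 8)), pos = 1:8 * 10L)
  win2 <- tajimas_d_windows(blk, blk$samples, window_bp = 1000,
                            step_bp = 1000)
  expect_gt(win2$d, 0)
})

test_that("Tajima's D agrees with the oracle on random matrices", {
  set.seed(51)
  for (r in 1:25) {
    n <- sample(5:15, 1)
    L <- sample(8:25, 1)
    g <- random_geno(n, L, pos = seq_len(L) * 11L)
    win <- tajimas_d_windows(g, g$samples, window_bp = 1e4, step_bp = 1e4)
    f <- allele_frequencies(g, g$samples)
    want <- oracle_tajima_d(f$freq, 2 * f$n)
    if (is.na(want)) expect_true(is.na(win$d[1])) else {
      expect_equal(win$d[1], want, tolerance = 1e-9)
    }
  }
})

test_that("windows without segregating sites have undefined D", {
  g <- make_geno(matrix(2L, 4, 6), pos = 1:6 * 10L)
  win <- tajimas_d_windows(g, g$samples, window_bp = 1000, step_bp = 1000)
  expect_true(is.na(win$d))
  expect_equal(win$S, 0L)
  # fewer than 3 usable sites flags low confidence
  g2 <- make_geno(matrix(c(0L, 1L, 1L, 2L), 2, 2), pos = c(10L, 20L))
  win2 <- tajimas_d_windows(g2, g2$samples, window_bp = 1000, step_bp = 1000,
                            min_alleles = 4)
  expect_true(win2$low_confidence)
})

test_that("pi follows the hand-computed per-bp normalization", {
  # one site, p = 0.5, 2 diploids (4 alleles), 100-bp window -> 1/150
  g <- make_geno(matrix(c(0L, 2L), 2, 1), pos = 50L)
  win <- pi_windows(g, g$samples, window_bp = 100, step_bp = 100,
                    min_alleles = 4)
  expect_equal(win$pi, 1 / 150, tolerance = 1e-12)
  # doubling the window length with the same sites halves pi
  win2 <- pi_windows(g, g$samples, window_bp = 200, step_bp = 200)
  expect_equal(win2$pi, win$pi / 2, tolerance = 1e-12)
  # no polymorphism -> pi = 0; allele-label flips change nothing
  mono <- make_geno(matrix(2L, 4, 3), pos = 1:3 * 10L)
  expect_equal(pi_windows(mono, mono$samples, 100, 100)$pi, 0)
  set.seed(52)
  g3 <- random_geno(10, 20, pos = 1:20 * 10L)
  flip <- g3; flip$dosage[, 1:10] <- 2L - flip$dosage[, 1:10]
  expect_equal(pi_windows(flip, flip$samples, 500, 500)$pi,
               pi_windows(g3, g3$samples, 500, 500)$pi, tolerance = 1e-12)
  expect_equal(pi_windows(g3, g3$samples, 500, 500)$pi,
               oracle_pi(allele_frequencies(g3, g3$samples)$freq,
                         rep(20, 20), 500), tolerance = 1e-9)
})

test_that("D is invariant to sample order", {
  set.seed(53)
  g <- random_geno(12, 15, pos = 1:15 * 10L)
  w1 <- tajimas_d_windows(g, g$samples, 1000, 1000)
  w2 <- tajimas_d_windows(g, rev(g$samples), 1000, 1000)
  expect_equal(w2$d, w1$d, tolerance = 1e-12)
})

test_that("region contrast assigns windows by midpoint and averages", {
  win <- tibble::tibble(chrom = "LG01",
                        start = c(1L, 1001L, 2001L, 3001L),
                        end = c(1000L, 2000L, 3000L, 4000L),
                        n_sites = 5L, d = c(1, 2, -1, -2))
  reg <- tibble::tibble(chrom = "LG01", start = 900L, end = 2600L,
                        name = "inv")
  ct <- region_contrast(win, reg, stat = "d")
  # midpoints 500, 1500, 2500, 3500 -> windows 2 and 3 inside
  expect_equal(ct$regions$mean_inside, mean(c(2, -1)))
  expect_equal(ct$regions$mean_outside, mean(c(1, -2)))
  expect_equal(ct$regions$mean_chromosome, 0)
  # uniform statistic: inside equals outside
  win$d <- 1
  ct2 <- region_contrast(win, reg, stat = "d")
  expect_equal(ct2$regions$mean_inside, ct2$regions$mean_outside)
  # region with no windows has a missing inside mean
  far <- tibble::tibble(chrom = "LG01", start = 99000L, end = 99900L,
                        name = "empty")
  ct3 <- region_contrast(win, far, stat = "d")
  expect_true(is.na(ct3$regions$mean_inside))
})

test_that("a balanced simulated inversion elevates D inside the region", {
  cfg <- sim_config(
    n_migratory = 400, n_coastal = 400, year_start = 0, year_end = 4,
    generation_time_years = 1, n_neutral_snps = 300, n_chromosomes = 1,
    chromosome_length_bp = 1e6, burn_in_generations = 20,
    migration = tibble::tibble(year_from = 0, year_to = 0, m_cm = 0, m_mc = 0),
    inversions = list(inversion_spec("inv", "LG01", 3e5, 6e5,
                                     n_block_snps = 80, tag_fidelity = 0.98,
                                     init_freq_migratory = 0.5,
                                     init_freq_coastal = 0.5)),
    sampling = data.frame(year = 4, population = "migratory", n = 40),
    age_range = c(0L, 0L), missingness = NULL, seed = 54
  )
  sim <- simulate_cohorts(cfg)
  win <- tajimas_d_windows(sim$geno, sim$geno$samples, window_bp = 50000)
  ct <- region_contrast(win, inversion_regions(cfg), stat = "d")
  expect_gt(ct$regions$mean_inside, ct$regions$mean_outside)
  # within one karyotype class the block is not balanced-polymorphic,
  # so inside-region D is not elevated
  der <- sim$truth$karyotypes$sample_id[sim$truth$karyotypes$karyotype ==
                                          "DERIVED"]
  if (length(der) >= 8) {
    win_d <- tajimas_d_windows(sim$geno, der, window_bp = 50000)
    ct_d <- region_contrast(win_d, inversion_regions(cfg), stat = "d")
    expect_lt(ct_d$regions$mean_inside - ct_d$regions$mean_outside,
              ct$regions$mean_inside - ct$regions$mean_outside)
  }
})
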