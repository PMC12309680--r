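test_that("HWE chi-square reproduces hand-computed statistics", {
  exact <- hwe_chisq(c(25, 50, 25))
  expect_equal(exact$chisq, 0)
  expect_equal(exact$p, 1)
  # no heterozygotes at p = 0.5: expected (25, 50, 25), chisq = 100
  none <- hwe_chisq(c(50, 0, 50))
  expect_equal(none$chisq, 100)
  expect_false(none$in_hwe)
  # monomorphic group is trivially in HWE
  mono <- hwe_chisq(c(0, 0, 40))
  expect_equal(mono$chisq, 0)
  small <- hwe_chisq(c(1, 2, 17))
  expect_true(small$small_expected)
  expect_error(hwe_chisq(c(-1, 2, 3)), "non-negative")
})

test_that("HWE rejection rate sits at the nominal level under neutrality", {
  set.seed(61)
  reject <- vapply(1:400, function(r) {
    p <- runif(1, 0.25, 0.75)
    counts <- table(factor(hwe_sample(100, p), levels = 0:2))
    hwe_chisq(as.integer(counts))$p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.09)
})

test_that("Fisher exact matches hypergeometric enumeration on 2x2", {
  ft <- genotype_freq_table(
    tibble::tibble(sample_id = sprintf("s%d", 1:10),
                   call = rep(c("DERIVED", "ANCESTRAL"), each = 5)),
    tibble::tibble(sample_id = sprintf("s%d", 1:10),
                   catch_year = rep(c(1907, 2014), each = 5)))
  res <- fisher_years(ft)
  expect_equal(res$overall_p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(sort(unique(res$letters$letters)), c("a", "b"))
})

test_that("identical groups share one letter at p = 1", {
  ft <- tibble::tibble(group = rep(c(1907, 1975, 2014), each = 3),
                       class = rep(c("ANCESTRAL", "HET", "DERIVED"), 3),
                       n = rep(c(10L, 20L, 10L), 3))
  res <- fisher_years(ft)
  expect_equal(res$overall_p, 1)
  expect_true(all(res$letters$letters == "a"))
  expect_true(all(res$pairwise$p_adjusted == 1))
})

test_that("letters separate exactly the significantly different groups", {
  # three groups: two alike, one extreme
  ft <- tibble::tibble(group = rep(c("g1", "g2", "g3"), each = 2),
                       class = rep(c("A", "B"), 3),
                       n = c(20L, 2L, 18L, 4L, 2L, 20L))
  res <- fisher_years(ft, alpha = 0.05)
  letters_of <- setNames(res$letters$letters, res$letters$group)
  share <- function(a, b) {
    length(intersect(strsplit(letters_of[[a]], "")[[1]],
                     strsplit(letters_of[[b]], "")[[1]])) > 0
  }
  for (j in seq_len(nrow(res$pairwise))) {
    expect_equal(share(res$pairwise$group1[j], res$pairwise$group2[j]),
                 res$pairwise$p_adjusted[j] >= 0.05)
  }
})

test_that("empty groups are dropped with a warning", {
  ft <- tibble::tibble(group = c("a", "a", "b", "b", "c"),
                       class = c("x", "y", "x", "y", "x"),
                       n = c(5L, 5L, 4L, 6L, 0L))
  expect_warning(res <- fisher_years(ft), "empty")
  expect_equal(nrow(res$letters), 2L)
  suppressWarnings(expect_error(fisher_years(ft[c(1, 2, 5), ]), "2 non-empty"))
})

test_that("Monte-Carlo Fisher p is stable across seeds on a fixed table", {
  tab <- tibble::tibble(group = rep(c("y1", "y2", "y3", "y4"), each = 3),
                        class = rep(c("A", "H", "D"), 4),
                        n = c(30L, 14L, 6L, 25L, 19L, 6L, 18L, 22L, 10L,
                              12L, 25L, 13L))
  p1 <- fisher_years(tab, mc_draws = 1e5, seed = 1)$overall_p
  p2 <- fisher_years(tab, mc_draws = 1e5, seed = 99)$overall_p
  expect_lt(abs(p1 - p2), 0.005)
})

test_that("hemoglobin diplotypes classify concordant and discordant pairs", {
  d <- rbind(c(0L, 0L), c(1L, 1L), c(2L, 2L), c(2L, 1L), c(0L, NA))
  g <- make_geno(d, pos = c(55L, 62L))
  cls <- hb_diplotype(g, list(chrom = "LG01", pos = 55),
                      list(chrom = "LG01", pos = 62))
  expect_equal(cls$class, c("Val-Ala", "HET-HET", "Met-Lys", "other", NA))
  expect_error(hb_diplotype(g, list(chrom = "LG01", pos = 55),
                            list(chrom = "LG01", pos = 99)), "not found")
})

test_that("Kruskal-Wallis/Dunn matches base R and handles ties", {
  df <- data.frame(g = rep(c("a", "b"), each = 3),
                   v = c(1, 2, 3, 10, 11, 12))
  res <- kruskal_dunn(df, v, g)
  base <- kruskal.test(v ~ g, data = df)
  expect_equal(res$h, unname(base$statistic), tolerance = 1e-12)
  expect_equal(res$p, base$p.value, tolerance = 1e-12)
  # maximal separation for n = 6 in two groups of three
  expect_equal(res$h, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2))
  # tie-corrected H agrees with base R under heavy ties
  df2 <- data.frame(g = rep(c("a", "b", "c"), each = 4),
                    v = c(1, 1, 2, 3, 2, 2, 3, 4, 1, 3, 3, 5))
  res2 <- kruskal_dunn(df2, v, g)
  base2 <- kruskal.test(v ~ g, data = df2)
  expect_equal(res2$h, unname(base2$statistic), tolerance = 1e-12)
  # degenerate all-tied input collapses to H = 0, p = 1
  df3 <- data.frame(g = rep(c("a", "b"), each = 3), v = rep(7, 6))
  res3 <- kruskal_dunn(df3, v, g)
  expect_equal(res3$h, 0)
  expect_equal(res3$p, 1)
  expect_error(kruskal_dunn(df3[1:3, ], v, g), "2 groups")
})

test_that("Kruskal-Wallis rejects at the nominal rate under the null", {
  set.seed(62)
  reject <- vapply(1:300, function(r) {
    df <- data.frame(g = rep(c("a", "b", "c"), each = 10), v = rnorm(30))
    kruskal_dunn(df, v, g)$p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.09)
})

test_that("Dunn pairwise z values are BH-adjusted and signed by rank means", {
  set.seed(63)
  df <- data.frame(g = rep(c("lo", "mid", "hi"), each = 8),
                   v = c(rnorm(8, 0), rnorm(8, 1.5), rnorm(8, 3)))
  res <- kruskal_dunn(df, v, g)
  pw <- tidy(res)
  expect_equal(pw$p_adjusted, p.adjust(pw$p, "BH"))
  hi_lo <- pw[pw$group1 == "hi" & pw$group2 == "lo", ]
  expect_gt(hi_lo$z, 0)
})
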