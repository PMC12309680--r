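#' Per-site allele frequencies for a sample set
#'
#' @param gm A [geno] object.
#' @param samples Character vector of sample ids.
#' @return Tibble with `chrom`, `pos`, `freq` (alternate-allele frequency
#'   over non-missing alleles; `NA` where every genotype is missing) and `n`
#'   (diploid count of non-missing samples).
#' @export
allele_frequencies <- function(gm, samples) {
  if (!length(samples)) stop("empty sample set", call. = FALSE)
  sub <- gm[samples, ]
  n <- unname(colSums(!is.na(sub$dosage)))
  freq <- ifelse(n > 0, unname(colSums(sub$dosage, na.rm = TRUE)) / (2 * n), NA_real_)
  dplyr::bind_cols(gm$sites[, c("chrom", "pos")],
                   tibble::tibble(freq = freq, n = n))
}

#' Temporal allele-frequency shift Fs' and effective population size
#'
#' The raw shift statistic is a ratio of sums across loci,
#' `Fs = sum((x - y)^2) / sum(z * (1 - z))` with `z = (x + y) / 2`, sites
#' monomorphic in the pooled pair excluded. Under sampling plan II (sampled
#' individuals are caught before reproducing, samples much smaller than the
#' census) the sampling-noise expectation is subtracted and rescaled:
#'
#' `Fs' = (Fs * (1 - 1/(4 * N)) - 1/N) / ((1 + Fs/4) * (1 - 1/(2 * n_t)))`
#'
#' where `N` is the harmonic-mean sample size and `n_t` the later sample's
#' mean size, both in diploid individuals (the individuals-vs-alleles
#' convention is fixed by the drift calibration: `E(Fs') = t/(2 Ne)`).
#' The standard error comes from a delete-one-locus jackknife on the
#' ratio-of-sums; the 95% CI is `Fs' +/- 1.96 SE`.
#'
#' @param gm A [geno] object.
#' @param samples_t0,samples_t1 Sample ids of the earlier and later sample.
#' @param t_generations Elapsed generations between the samples (> 0).
#' @param ratio_of_sums If `FALSE`, use the unweighted mean of per-locus
#'   ratios instead (not recommended: it does not calibrate at low-MAF loci).
#' @return A one-row tibble of class `fs_result`: `fs_raw`, `fs_prime`,
#'   `se`, `ci_low`, `ci_high`, `n_harmonic` (diploid individuals),
#'   `n_loci`, `t_generations`, `ne_estimate` (`Inf` when `fs_prime <= 0`).
#' @export
#' @examples
#' g <- geno(matrix(c(0L, 1L, 2L, 0L, 1L, 2L, 2L, 2L, 2L, 0L, 0L, 0L), 4, 3),
#'           sites = data.frame(chrom = "LG01", pos = c(1L, 2L, 3L),
#'                              ref = "A", alt = "C"),
#'           samples = c("a", "b", "c", "d"))
#' fs_prime(g, c("a", "b"), c("c", "d"), t_generations = 2)
fs_prime <- function(gm, samples_t0, samples_t1, t_generations,
                     ratio_of_sums = TRUE) {
  if (t_generations <= 0) stop("t_generations must be > 0", call. = FALSE)
  f0 <- allele_frequencies(gm, samples_t0)
  f1 <- allele_frequencies(gm, samples_t1)
  x <- f0$freq; y <- f1$freq
  z <- (x + y) / 2
  usable <- !is.na(z) & z > 0 & z < 1
  if (sum(usable) < 2) stop("fewer than 2 usable (polymorphic) loci", call. = FALSE)
  x <- x[usable]; y <- y[usable]; z <- z[usable]
  n0 <- f0$n[usable]; n1 <- f1$n[usable]

  num <- (x - y)^2
  den <- z * (1 - z)
  correct <- function(fs, nh, nt) {
    (fs * (1 - 1 / (4 * nh)) - 1 / nh) / ((1 + fs / 4) * (1 - 1 / (2 * nt)))
  }
  n0_bar <- mean(n0); n1_bar <- mean(n1)
  nh <- 2 / (1 / n0_bar + 1 / n1_bar)
  if (ratio_of_sums) {
    fs_raw <- sum(num) / sum(den)
  } else {
    fs_raw <- mean(num / den)
  }
  fsp <- correct(fs_raw, nh, n1_bar)

  # delete-one-locus jackknife on the full estimator
  L <- length(num)
  if (ratio_of_sums) {
    fs_i <- (sum(num) - num) / (sum(den) - den)
  } else {
    fs_i <- (sum(num / den) - num / den) / (L - 1)
  }
  n0_i <- (sum(n0) - n0) / (L - 1)
  n1_i <- (sum(n1) - n1) / (L - 1)
  nh_i <- 2 / (1 / n0_i + 1 / n1_i)
  fsp_i <- correct(fs_i, nh_i, n1_i)
  se <- sqrt((L - 1) / L * sum((fsp_i - mean(fsp_i))^2))

  out <- tibble::tibble(
    fs_raw = fs_raw, fs_prime = fsp, se = se,
    ci_low = fsp - 1.96 * se, ci_high = fsp + 1.96 * se,
    n_harmonic = nh, n_loci = L, t_generations = t_generations,
    ne_estimate = estimate_ne(fsp, t_generations)
  )
  class(out) <- c("fs_result", class(out))
  out
}

#' Effective population size from a corrected temporal shift
#'
#' `Ne = t / (2 * Fs')` for positive `Fs'`; a shift at or below zero means
#' the observed frequency differences are within sampling noise, and the
#' drift-based estimate is infinity.
#'
#' @param fs_prime_value Corrected Fs' value.
#' @param t_generations Elapsed generations (> 0).
#' @return Diploid effective size, possibly `Inf`.
#' @export
#' @examples
#' estimate_ne(0.01, 10)   # 500
#' estimate_ne(-9e-05, 13) # Inf
estimate_ne <- function(fs_prime_value, t_generations) {
  if (t_generations <= 0) stop("t_generations must be > 0", call. = FALSE)
  ifelse(fs_prime_value > 0, t_generations / (2 * fs_prime_value), Inf)
}

#' Temporal shifts for many year pairs
#'
#' Convenience wrapper running [fs_prime()] for each pair of sampling years
#' of one population, converting year spans to generations.
#'
#' @param gm A [geno] object.
#' @param meta Metadata with `sample_id`, `population`, `catch_year`.
#' @param population Population label to analyse.
#' @param pairs Data frame with columns `year0`, `year1`; `NULL` for all
#'   pairs of observed sampling years.
#' @param generation_time_years Years per generation.
#' @return An `fs_result` tibble, one row per pair, with `year0`, `year1`.
#' @export
fs_prime_pairs <- function(gm, meta, population, pairs = NULL,
                           generation_time_years) {
  meta <- meta[meta$population == population & meta$sample_id %in% gm$samples, ]
  years <- sort(unique(meta$catch_year))
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(year0 = years, year1 = years)
    pairs <- pairs[pairs$year0 < pairs$year1, ]
  }
  res <- purrr::pmap(pairs, function(year0, year1) {
    t_gen <- max(1L, round((year1 - year0) / generation_time_years))
    r <- fs_prime(gm,
                  meta$sample_id[meta$catch_year == year0],
                  meta$sample_id[meta$catch_year == year1],
                  t_generations = t_gen)
    dplyr::bind_cols(tibble::tibble(year0 = year0, year1 = year1), r)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("fs_result", class(out))
  out
}

#' Plot temporal shifts per year pair
#'
#' @param object An `fs_result` tibble from [fs_prime_pairs()].
#' @param ... Unused.
#' @return A ggplot object: point estimate with 95% CI per pair, positive
#'   shifts highlighted.
#' @export
autoplot.fs_result <- function(object, ...) {
  if (!all(c("year0", "year1") %in% names(object))) {
    stop("autoplot needs the multi-pair form from fs_prime_pairs()", call. = FALSE)
  }
  df <- object
  df$pair <- paste(df$year0, df$year1, sep = "–")
  df$sign <- ifelse(df$fs_prime > 0, "positive", "non-positive")
  ggplot2::ggplot(df, ggplot2::aes(.data$pair, .data$fs_prime,
                                   colour = .data$sign)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_colour_manual(values = c(positive = "darkorange",
                                            `non-positive` = "grey30")) +
    ggplot2::labs(x = NULL, y = "Fs'") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' One-row summary of a temporal-shift fit
#' @param x An `fs_result` tibble.
#' @param ... Unused.
#' @return Tibble with pair count and the range of Ne estimates.
#' @export
glance.fs_result <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x),
                 n_positive = sum(x$fs_prime > 0),
                 ne_min = min(x$ne_estimate), ne_max = max(x$ne_estimate))
}
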