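#' Windowed Tajima's D
#'
#' Genotype-based (unphased) Tajima's D in sliding windows. Per window,
#' `S` is the count of segregating sites, the Watterson estimator is
#' `S / a1`, and the pairwise estimator is the sum over segregating sites of
#' `2 p (1 - p) n / (n - 1)` with `p` the alternate-allele frequency and `n`
#' the site's non-missing allele count. The standard constants
#' `a1, a2, b1, b2, c1, c2, e1, e2` are evaluated at the window's
#' harmonic-mean allele count (rounded to the nearest integer under
#' missingness). Windows with `S = 0` are emitted with `D` missing; windows
#' with fewer than 3 usable sites are flagged low-confidence.
#'
#' @param gm A [geno] object (unpruned, without MAF filtering).
#' @param samples Sample ids of the group (e.g. one population-year).
#' @param window_bp Window size in bp (default 30 kb).
#' @param step_bp Step (default half the window).
#' @param min_alleles Minimum non-missing alleles for a site to be used.
#' @return Tibble with `chrom`, `start`, `end`, `n_sites`, `S`, `d`,
#'   `low_confidence`.
#' @export
tajimas_d_windows <- function(gm, samples, window_bp = 30000,
                              step_bp = window_bp / 2, min_alleles = 4) {
  tb <- site_diversity_table(gm, samples, min_alleles)
  out <- window_stat(tb, window_bp, step_bp, function(rows) {
    tajima_d_from_sites(rows$p, rows$n_alleles)
  }, value_name = "d")
  out$S <- window_stat(tb, window_bp, step_bp, function(rows) {
    sum(rows$p > 0 & rows$p < 1)
  }, value_name = "S")$S
  out$low_confidence <- out$n_sites < 3
  out[, c("chrom", "start", "end", "n_sites", "S", "d", "low_confidence")]
}

# per-site usable frequencies and allele counts for one sample group
site_diversity_table <- function(gm, samples, min_alleles = 4) {
  f <- allele_frequencies(gm, samples)
  f$n_alleles <- 2 * f$n
  f <- f[!is.na(f$freq) & f$n_alleles >= min_alleles, ]
  names(f)[names(f) == "freq"] <- "p"
  f
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

tajima_d_from_sites <- function(p, n_alleles) {
  seg <- p > 0 & p < 1
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  theta_pi <- sum(2 * p[seg] * (1 - p[seg]) * n_alleles[seg] / (n_alleles[seg] - 1))
  n_h <- round(length(n_alleles) / sum(1 / n_alleles))
  if (n_h < 2) return(NA_real_)
  k <- tajima_constants(n_h)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (theta_pi - S / k$a1) / sqrt(v)
}

#' Windowed nucleotide diversity
#'
#' Per-bp nucleotide diversity: the per-site heterozygosity
#' `2 p (1 - p) n / (n - 1)` summed over genotyped sites in the window and
#' divided by the window length in bp (monomorphic and unobserved positions
#' contribute zero). Windows without genotyped sites are omitted.
#'
#' @inheritParams tajimas_d_windows
#' @param window_bp Window size in bp (default 50 kb).
#' @return Tibble with `chrom`, `start`, `end`, `n_sites`, `pi`.
#' @export
pi_windows <- function(gm, samples, window_bp = 50000,
                       step_bp = window_bp / 2, min_alleles = 4) {
  tb <- site_diversity_table(gm, samples, min_alleles)
  window_stat(tb, window_bp, step_bp, function(rows) {
    sum(2 * rows$p * (1 - rows$p) * rows$n_alleles / (rows$n_alleles - 1)) /
      window_bp
  }, value_name = "pi")
}

#' Inside-versus-outside-region contrast of a windowed statistic
#'
#' Assigns each window inside a region if its midpoint falls within the
#' region (1-based inclusive), then reports the mean statistic inside each
#' region, outside all regions (per chromosome) and chromosome-wide. The
#' classic use is contrasting Tajima's D inside an inversion against the
#' rest of the chromosome: balanced inversion polymorphism elevates D inside.
#'
#' @param windows A window table (e.g. from [tajimas_d_windows()]).
#' @param regions Regions with `chrom`, `start`, `end`, `name`.
#' @param stat Statistic column name; default: last non-coordinate column.
#' @return A list with `regions` (tibble: `name`, `chrom`, `n_windows`,
#'   `mean_inside`, `mean_outside`, `mean_chromosome`) and `windows` (the
#'   input with an `inside` label column).
#' @export
region_contrast <- function(windows, regions, stat = NULL) {
  if (is.null(stat)) {
    stat <- setdiff(names(windows), c("chrom", "start", "end", "n_sites",
                                      "S", "low_confidence", "p", "q"))[1]
  }
  regions <- tibble::as_tibble(regions)
  if (!"name" %in% names(regions)) {
    regions$name <- paste0("region_", seq_len(nrow(regions)))
  }
  mid <- (windows$start + windows$end) / 2
  windows$inside <- NA_character_
  for (i in seq_len(nrow(regions))) {
    hit <- windows$chrom == regions$chrom[i] & mid >= regions$start[i] &
      mid <= regions$end[i]
    windows$inside[hit] <- regions$name[i]
  }
  x <- windows[[stat]]
  summ <- purrr::map(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]
    on_ch <- windows$chrom == ch
    ins <- on_ch & !is.na(windows$inside) & windows$inside == regions$name[i]
    tibble::tibble(
      name = regions$name[i], chrom = ch,
      n_windows = sum(ins),
      mean_inside = if (any(ins)) mean(x[ins], na.rm = TRUE) else NA_real_,
      mean_outside = mean(x[on_ch & is.na(windows$inside)], na.rm = TRUE),
      mean_chromosome = mean(x[on_ch], na.rm = TRUE)
    )
  })
  list(regions = dplyr::bind_rows(summ), windows = windows)
}
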