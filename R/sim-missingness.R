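#' Degrade genotypes to emulate low-coverage historical samples
#'
#' Each genotype is independently set to missing with an era-specific rate,
#' and each retained genotype is perturbed to a random *other* dosage with an
#' era-specific genotyping-error rate. Eras are defined by catch year: a
#' sample belongs to the first schedule row whose `year_to` is at or after
#' its catch year.
#'
#' @param gm A [geno] object.
#' @param meta Sample metadata with `sample_id` and `catch_year` (e.g. the
#'   `samples` table of [simulate_cohorts()]).
#' @param schedule Data frame with columns `year_to`, `miss_rate`,
#'   `error_rate`; rows must be ordered by `year_to` and the last row should
#'   have `year_to = Inf` to cover all samples.
#' @param seed Integer seed; counts are reproducible under a fixed seed.
#' @return A [geno] object with the same dimensions.
#' @export
#' @examples
#' cfg <- sim_config(n_neutral_snps = 50, n_chromosomes = 1, inversions = list(),
#'                   n_migratory = 100, n_coastal = 100,
#'                   sampling = data.frame(year = 1907, population = "migratory",
#'                                         n = 10))
#' sim <- simulate_cohorts(cfg)
#' degraded <- inject_missingness(sim$geno, sim$samples,
#'                                data.frame(year_to = Inf, miss_rate = 0.2,
#'                                           error_rate = 0.01), seed = 1)
#' mean(is.na(degraded$dosage))
inject_missingness <- function(gm, meta, schedule, seed = 1L) {
  schedule <- tibble::as_tibble(schedule)
  stopifnot(all(schedule$miss_rate >= 0 & schedule$miss_rate <= 1),
            all(schedule$error_rate >= 0 & schedule$error_rate <= 1))
  meta <- meta[match(gm$samples, meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata is missing some samples", call. = FALSE)
  era <- vapply(meta$catch_year,
                function(y) which(y <= schedule$year_to)[1], 1L)
  if (anyNA(era)) stop("missingness schedule does not cover all catch years",
                       call. = FALSE)
  withr::with_seed(seed, {
    d <- gm$dosage
    for (i in seq_len(nrow(d))) {
      mr <- schedule$miss_rate[era[i]]
      er <- schedule$error_rate[era[i]]
      row <- d[i, ]
      if (mr > 0) row[stats::runif(length(row)) < mr] <- NA_integer_
      if (er > 0) {
        flip <- which(!is.na(row) & stats::runif(length(row)) < er)
        if (length(flip)) {
          row[flip] <- vapply(row[flip],
                              function(x) sample(setdiff(0:2, x), 1L), 1L)
        }
      }
      d[i, ] <- row
    }
    gm$dosage <- d
    gm
  })
}
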