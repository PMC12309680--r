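#' Genotype-level site and sample filters
#'
#' Applies, in order: restriction to biallelic sites (sites whose ref/alt
#' are single bases; multiallelic records are already dropped at VCF read),
#' removal of sites with high missingness, removal of samples with high
#' missingness, a minor-allele-frequency floor (computed on non-missing
#' alleles), and optionally removal of C/T and G/A ref-alt pairs (the
#' transition classes produced by post-mortem cytosine deamination in
#' historical DNA). Depth- and mappability-based steps of a full
#' variant-calling pipeline require BAMs and are documented as upstream.
#'
#' @param gm A [geno] object.
#' @param biallelic_only Drop sites whose alleles are not single A/C/G/T bases.
#' @param max_site_missing Maximum fraction of missing genotypes per site.
#' @param max_sample_missing Maximum fraction of missing genotypes per sample.
#' @param maf Minor-allele-frequency floor in `[0, 0.5)`.
#' @param drop_transitions If `TRUE`, drop sites whose ref/alt pair is C/T or
#'   G/A (in either order).
#' @return A filtered [geno]; the removal counts per rule are available via
#'   [filter_report()].
#' @export
#' @examples
#' g <- geno(matrix(c(0L, NA, NA, NA, 0L, 2L), 2, 3),
#'           sites = data.frame(chrom = "LG01", pos = c(1L, 5L, 9L),
#'                              ref = c("A", "C", "G"), alt = c("C", "T", "T")),
#'           samples = c("s1", "s2"))
#' f <- filter_sites(g, max_site_missing = 0.5, drop_transitions = TRUE)
#' filter_report(f)
filter_sites <- function(gm, biallelic_only = TRUE, max_site_missing = 0.5,
                         max_sample_missing = 0.8, maf = 0,
                         drop_transitions = FALSE) {
  if (maf >= 0.5) stop("MAF floor must be below 0.5", call. = FALSE)
  report <- list()
  n0 <- n_sites(gm)
  if (biallelic_only) {
    ok <- gm$sites$ref %in% c("A", "C", "G", "T") &
      gm$sites$alt %in% c("A", "C", "G", "T") & gm$sites$ref != gm$sites$alt
    gm <- keep_sites(gm, ok)
    report$biallelic <- n0 - n_sites(gm)
  }
  site_miss <- colMeans(is.na(gm$dosage))
  n0 <- n_sites(gm)
  gm <- keep_sites(gm, site_miss <= max_site_missing)
  report$site_missingness <- n0 - n_sites(gm)

  sample_miss <- rowMeans(is.na(gm$dosage))
  drop_sam <- sample_miss > max_sample_missing
  report$sample_missingness <- sum(drop_sam)
  if (any(drop_sam)) gm <- gm[!drop_sam, ]

  freq <- site_freqs(gm)
  minor <- pmin(freq, 1 - freq)
  n0 <- n_sites(gm)
  gm <- keep_sites(gm, !is.na(minor) & minor >= maf)
  report$maf <- n0 - n_sites(gm)

  if (drop_transitions) {
    pair <- paste0(pmin(gm$sites$ref, gm$sites$alt),
                   pmax(gm$sites$ref, gm$sites$alt))
    n0 <- n_sites(gm)
    gm <- keep_sites(gm, !(pair %in% c("CT", "AG")))
    report$transitions <- n0 - n_sites(gm)
  }
  attr(gm, "filter_report") <- tibble::tibble(
    rule = names(report), removed = unlist(report, use.names = FALSE)
  )
  gm
}

#' Removal counts of the last filtering step
#'
#' @param gm A [geno] returned by [filter_sites()].
#' @return Tibble with columns `rule` and `removed` (sites for site rules,
#'   samples for the sample-missingness rule), in application order.
#' @export
filter_report <- function(gm) {
  rep <- attr(gm, "filter_report")
  if (is.null(rep)) stop("no filter report attached; run filter_sites() first",
                         call. = FALSE)
  rep
}

# alt-allele frequency per site over non-missing alleles (NaN if all missing)
site_freqs <- function(gm) {
  unname(colSums(gm$dosage, na.rm = TRUE) / (2 * colSums(!is.na(gm$dosage))))
}

#' Greedy sliding-window LD pruning
#'
#' Within each sliding window of `window_snps` sites (advanced by
#' `step_snps`), any pair of retained sites with squared Pearson correlation
#' of dosages above `r2_max` (computed over pairwise-complete samples) loses
#' its downstream member. After pruning, every remaining pair within any
#' window satisfies r-squared at or below the threshold. Defaults mirror the
#' common plink choice `--indep-pairwise 50 5 0.5`.
#'
#' @param gm A [geno] object.
#' @param window_snps Window size in SNPs.
#' @param step_snps Step in SNPs; must not exceed the window.
#' @param r2_max Squared-correlation threshold in (0, 1).
#' @return A pruned [geno] object.
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 5, r2_max = 0.5) {
  stopifnot(window_snps >= step_snps, step_snps >= 1,
            r2_max > 0, r2_max < 1)
  keep <- rep(TRUE, n_sites(gm))
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    starts <- seq(1L, max(1L, length(idx)), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(
        stats::cor(gm$dosage[, win, drop = FALSE],
                   use = "pairwise.complete.obs")^2)
      for (a in seq_len(length(win) - 1L)) {
        if (!keep[win[a]]) next
        for (b in seq(a + 1L, length(win))) {
          if (keep[win[b]] && !is.na(r2[a, b]) && r2[a, b] > r2_max) {
            keep[win[b]] <- FALSE
          }
        }
      }
      if (s + window_snps - 1L >= length(idx)) break
    }
  }
  keep_sites(gm, keep)
}

#' Drop or keep sites falling in genomic regions
#'
#' `exclude_regions()` removes sites inside any of the given intervals (used
#' to build the neutral, inversion-excluded dataset); `restrict_to_regions()`
#' is the complement (used for karyotyping). Regions use 1-based inclusive
#' coordinates as returned by [read_bed()].
#'
#' @param gm A [geno] object.
#' @param regions Data frame with `chrom`, `start`, `end` (1-based inclusive).
#' @return A [geno] object.
#' @export
exclude_regions <- function(gm, regions) {
  keep_sites(gm, !sites_in_regions(gm, regions))
}

#' @rdname exclude_regions
#' @export
restrict_to_regions <- function(gm, regions) {
  keep_sites(gm, sites_in_regions(gm, regions))
}

sites_in_regions <- function(gm, regions) {
  hit <- rep(FALSE, n_sites(gm))
  if (is.null(regions) || nrow(regions) == 0) return(hit)
  unknown <- setdiff(unique(regions$chrom), unique(gm$sites$chrom))
  if (length(unknown)) {
    warning("ignoring regions on unknown chromosome(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (gm$sites$chrom == regions$chrom[i] &
                    gm$sites$pos >= regions$start[i] &
                    gm$sites$pos <= regions$end[i])
  }
  hit
}
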