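#' Heterozygous-site fraction per sample
#'
#' Fraction of non-missing sites at which a sample is heterozygous
#' (dosage 1), optionally restricted to a region. Used to validate inversion
#' karyotype calls: heterokaryotypes are heterozygous across the whole
#' inverted block, so the HET cluster must show the highest fraction.
#'
#' @param gm A [geno] object.
#' @param region Optional single region (`chrom`, `start`, `end`, 1-based
#'   inclusive) to restrict to.
#' @return Tibble with `sample_id`, `n_sites` (non-missing), `het_fraction`
#'   (`NA` if every site is missing for the sample).
#' @export
het_fraction <- function(gm, region = NULL) {
  if (!is.null(region)) {
    gm <- restrict_to_regions(gm, tibble::as_tibble(region))
    if (n_sites(gm) == 0) stop("region contains no sites", call. = FALSE)
  }
  n_obs <- unname(rowSums(!is.na(gm$dosage)))
  n_het <- unname(rowSums(gm$dosage == 1L, na.rm = TRUE))
  tibble::tibble(sample_id = gm$samples, n_sites = n_obs,
                 het_fraction = ifelse(n_obs > 0, n_het / n_obs, NA_real_))
}

#' Call inversion karyotypes from PC1 clusters
#'
#' For each inversion region: restrict the genotype matrix to its sites, run
#' [run_pca()], and cluster the PC1 scores into three groups by 1-D k-means
#' with deterministic initialization at the 10/50/90th percentiles. The
#' middle cluster is HET. The outer clusters are polarized by an anchor — a
#' sample or population known to carry the DERIVED arrangement — or, absent
#' an anchor, by mean alternate-allele dosage (arbitrary-but-consistent,
#' flagged `anchored = FALSE`). Calls whose cluster-assignment confidence
#' (one minus the ratio of the distances to the nearest and second-nearest
#' centre) falls below `min_confidence` are returned as `NA` and flagged
#' ambiguous. If the centres are separated by less than `min_separation`
#' within-cluster standard deviations, all calls for that inversion are
#' flagged low-confidence.
#'
#' @param gm A [geno] object (not LD-pruned; karyotyping needs the block LD).
#' @param regions Inversion regions: `chrom`, `start`, `end`, `name`
#'   (1-based inclusive), e.g. from [inversion_regions()] or [read_bed()].
#' @param anchor Optional character vector of sample ids known to be
#'   homozygous DERIVED (or predominantly so), used to polarize the outer
#'   clusters.
#' @param min_sites Minimum polymorphic sites per region (default 10).
#' @param min_confidence Confidence floor below which a call is ambiguous.
#' @param min_separation Required centre separation in units of pooled
#'   within-cluster standard deviation (default 4; genuine karyotype
#'   clusters separate by far more, a unimodal score distribution by less).
#' @return Tibble of class `karyotype_calls`: `sample_id`, `inversion`,
#'   `pc1`, `het_fraction`, `call` (`ANCESTRAL`/`HET`/`DERIVED` or `NA`),
#'   `confidence`, `anchored`, `low_confidence`.
#' @export
call_karyotypes <- function(gm, regions, anchor = NULL, min_sites = 10,
                            min_confidence = 0.05, min_separation = 4) {
  regions <- tibble::as_tibble(regions)
  if (!"name" %in% names(regions)) {
    regions$name <- paste0("region_", seq_len(nrow(regions)))
  }
  out <- purrr::map(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    sub <- restrict_to_regions(gm, reg)
    p <- site_freqs(sub)
    n_poly <- sum(!is.na(p) & p > 0 & p < 1)
    if (n_poly < min_sites) {
      stop("region ", reg$name, " has ", n_poly,
           " polymorphic sites; need at least ", min_sites, call. = FALSE)
    }
    pca <- run_pca(sub, k = 1)
    pc1 <- pca$scores$PC1
    cl <- kmeans3_1d(pc1)
    het <- het_fraction(sub)$het_fraction

    # order clusters along PC1: middle one is HET
    ord <- order(cl$centers)
    rank_of <- match(seq_along(cl$centers), ord)  # cluster id -> position 1..3
    position <- rank_of[cl$cluster]               # 1 = low, 2 = mid, 3 = high

    # polarize outer clusters
    if (!is.null(anchor)) {
      anchored <- TRUE
      a_pos <- position[gm$samples %in% anchor]
      a_pos <- a_pos[a_pos != 2]
      derived_pos <- if (length(a_pos)) {
        as.integer(names(which.max(table(a_pos))))
      } else 3L
    } else {
      anchored <- FALSE
      mean_dos <- tapply(rowMeans(sub$dosage, na.rm = TRUE), position, mean)
      hi <- if ("3" %in% names(mean_dos)) mean_dos[["3"]] else -Inf
      lo <- if ("1" %in% names(mean_dos)) mean_dos[["1"]] else -Inf
      derived_pos <- if (hi >= lo) 3L else 1L
    }
    lab <- c("ANCESTRAL", "HET", "DERIVED")[match(position, c(
      setdiff(c(1L, 3L), derived_pos), 2L, derived_pos))]

    # confidence: 1 - d(nearest centre)/d(second-nearest centre)
    d <- abs(outer(pc1, cl$centers, "-"))
    d_sorted <- t(apply(d, 1, sort))
    confidence <- ifelse(d_sorted[, 2] > 0, 1 - d_sorted[, 1] / d_sorted[, 2], 1)
    lab[confidence < min_confidence] <- NA_character_

    within_sd <- sqrt(mean((pc1 - cl$centers[cl$cluster])^2))
    sep <- min(diff(sort(cl$centers)))
    low_conf <- length(unique(cl$cluster)) < 3 ||
      (within_sd > 0 && sep < min_separation * within_sd)

    tibble::tibble(sample_id = sub$samples, inversion = reg$name, pc1 = pc1,
                   het_fraction = het, call = lab, confidence = confidence,
                   anchored = anchored, low_confidence = low_conf)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("karyotype_calls", class(out))
  out
}

# deterministic 1-D Lloyd k-means, k = 3, centres initialized at the
# 10/50/90th percentiles
kmeans3_1d <- function(x, max_iter = 100) {
  centers <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  cluster <- rep(1L, length(x))
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    new_cluster <- max.col(-d, ties.method = "first")
    if (identical(new_cluster, cluster) && it > 1) break
    cluster <- new_cluster
    for (k in 1:3) {
      if (any(cluster == k)) centers[k] <- mean(x[cluster == k])
    }
  }
  list(cluster = cluster, centers = centers)
}

#' Plot karyotype calls: PC1 against heterozygosity
#'
#' The standard validation plot for PCA-based inversion genotyping: three
#' clusters on PC1, with the middle (HET) cluster at the highest
#' heterozygous-site fraction.
#'
#' @param object A `karyotype_calls` tibble from [call_karyotypes()].
#' @param ... Unused.
#' @return A ggplot object, faceted by inversion.
#' @export
autoplot.karyotype_calls <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pc1, .data$het_fraction,
                                       colour = .data$call)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~inversion, scales = "free_x") +
    ggplot2::labs(x = "PC1", y = "heterozygous-site fraction") +
    ggplot2::theme_minimal()
}
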