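#' Genotype principal component analysis
#'
#' Standard population-genetic PCA: each site is centered by twice its
#' non-missing alternate-allele frequency `2 * p` and scaled by
#' `sqrt(p * (1 - p))`; missing dosages are mean-imputed (contributing zero
#' after centering); monomorphic sites are dropped. The sample covariance
#' matrix (over sites) is eigendecomposed. Each axis is deterministically
#' oriented so that the mean score of the first group (or the first sample,
#' if no groups are given) is non-positive.
#'
#' @param gm A [geno] object with at least two samples and two polymorphic
#'   sites.
#' @param k Number of axes to return.
#' @param groups Optional factor/character vector (one per sample) used only
#'   for the sign-orientation rule.
#' @return An object of class `geno_pca` with elements `scores` (tibble:
#'   `sample_id`, `PC1`, ...), `explained` (per-axis explained-variance
#'   fractions), `loadings` (tibble of per-site loadings) and `center`/`scale`
#'   vectors (the normalization record).
#' @export
run_pca <- function(gm, k = 10, groups = NULL) {
  if (n_samples(gm) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  p <- site_freqs(gm)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all sites are monomorphic", call. = FALSE)
  gm2 <- keep_sites(gm, poly)
  p <- p[poly]
  x <- sweep(gm2$dosage, 2, 2 * p)
  x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  x[is.na(x)] <- 0
  n <- nrow(x)
  k <- min(k, n - 1L, ncol(x))
  cv <- tcrossprod(x) / ncol(x)
  eig <- eigen(cv, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  expl <- lambda / sum(lambda)
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  scores <- sweep(vec, 2, sqrt(lambda[seq_len(k)]), "*")
  # deterministic sign orientation
  ref <- if (is.null(groups)) 1L else which(groups == groups[1])
  for (a in seq_len(k)) {
    if (mean(scores[ref, a]) > 0) {
      scores[, a] <- -scores[, a]
      vec[, a] <- -vec[, a]
    }
  }
  loadings <- crossprod(x, vec)
  loadings <- sweep(loadings, 2, sqrt(colSums(loadings^2)), "/")
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = gm2$samples),
                              tibble::as_tibble(scores)),
    explained = expl[seq_len(k)],
    loadings = dplyr::bind_cols(gm2$sites[, c("chrom", "pos")],
                                tibble::as_tibble(loadings)),
    center = 2 * p, scale = sqrt(p * (1 - p)),
    n_sites = ncol(x)
  ), class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d samples, %d sites, %d axes\n",
              nrow(x$scores), x$n_sites, length(x$explained)))
  cat("  explained variance:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$explained, 5)),
             collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-sample PCA scores
#' @param x A `geno_pca` object.
#' @param ... Unused.
#' @return Tibble with `sample_id` and one column per axis.
#' @export
tidy.geno_pca <- function(x, ...) x$scores

#' One-row PCA summary
#' @param x A `geno_pca` object.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `n_sites`, `k`, `pve1`..`pve3`.
#' @export
glance.geno_pca <- function(x, ...) {
  pve <- c(x$explained, rep(NA_real_, 3))
  tibble::tibble(n_samples = nrow(x$scores), n_sites = x$n_sites,
                 k = length(x$explained),
                 pve1 = pve[1], pve2 = pve[2], pve3 = pve[3])
}

#' Plot the first two PCA axes
#' @param object A `geno_pca` object.
#' @param groups Optional vector (one per sample) mapped to colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.geno_pca <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}
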