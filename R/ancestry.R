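#' Reference-panel allele frequencies
#'
#' Per-panel, per-site alternate-allele frequencies for supervised ancestry
#' estimation, clipped away from 0 and 1 (default epsilon `1/(2n + 2)`) so
#' the mixture log-likelihood stays finite.
#'
#' @param gm A [geno] object.
#' @param panels Named list of character vectors of sample ids; each panel
#'   needs at least `min_panel` samples.
#' @param eps Clipping bound; `NULL` for the per-panel default.
#' @param min_panel Minimum panel size (default 5).
#' @return Tibble with `chrom`, `pos` and one frequency column per panel;
#'   panel names are preserved.
#' @export
panel_freqs <- function(gm, panels, eps = NULL, min_panel = 5) {
  stopifnot(is.list(panels), !is.null(names(panels)))
  out <- gm$sites[, c("chrom", "pos")]
  for (nm in names(panels)) {
    ids <- panels[[nm]]
    if (length(ids) < min_panel) {
      stop("panel '", nm, "' has ", length(ids), " samples; need at least ",
           min_panel, call. = FALSE)
    }
    f <- allele_frequencies(gm, ids)
    e <- if (is.null(eps)) 1 / (2 * length(ids) + 2) else eps
    out[[nm]] <- pmin(pmax(f$freq, e), 1 - e)
  }
  out
}

#' Supervised ancestry proportions by maximum likelihood
#'
#' For each sample, maximizes the binomial mixture log-likelihood
#' `sum_sites log P(g | p_tilde)` with `g ~ Binomial(2, p_tilde)` and
#' `p_tilde = sum_k q_k p_k`, over the ancestry proportion vector `q` on the
#' simplex, by expectation-maximization from a uniform start (deterministic).
#' Missing genotypes are dropped per site. This is the supervised stand-in
#' for an unsupervised admixture analysis: proportions are estimated
#' relative to user-chosen reference panels.
#'
#' @param gm A [geno] object.
#' @param freqs Panel frequencies from [panel_freqs()].
#' @param samples Sample ids to estimate; default all samples of `gm`.
#' @param min_informative Floor on non-missing sites with panel frequency
#'   differences; samples below it are flagged.
#' @param tol Stop when the log-likelihood gain drops below this.
#' @param max_iter Iteration cap; non-convergence flags the result and
#'   returns the best iterate.
#' @return Tibble of class `ancestry_q`: `sample_id`, one `q_<panel>`
#'   column per panel, `loglik`, `n_sites`, `n_informative`, `converged`.
#' @export
fit_q <- function(gm, freqs, samples = NULL, min_informative = 100,
                  tol = 1e-8, max_iter = 1000, trace = FALSE) {
  panel_names <- setdiff(names(freqs), c("chrom", "pos"))
  K <- length(panel_names)
  if (K < 2) stop("need at least 2 panels", call. = FALSE)
  key_g <- paste(gm$sites$chrom, gm$sites$pos)
  key_f <- paste(freqs$chrom, freqs$pos)
  m <- match(key_g, key_f)
  if (anyNA(m)) stop("panel frequencies do not cover all sites", call. = FALSE)
  P <- as.matrix(freqs[m, panel_names])
  informative <- apply(P, 1, function(x) max(x) - min(x)) > 0
  if (is.null(samples)) samples <- gm$samples

  rows <- purrr::map(samples, function(id) {
    g <- gm$dosage[match(id, gm$samples), ]
    obs <- !is.na(g)
    gg <- g[obs]
    PP <- P[obs, , drop = FALSE]
    M <- length(gg)
    q <- rep(1 / K, K)
    ll_const <- sum(log(choose(2, gg)))
    ll_old <- -Inf
    converged <- FALSE
    ll_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      pt <- as.vector(PP %*% q)
      ll <- sum(gg * log(pt) + (2 - gg) * log(1 - pt)) + ll_const
      if (trace) ll_trace[it] <- ll
      if (it > 1 && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
      # EM: expected ancestry of alt and ref allele copies per site
      w_alt <- sweep(PP, 2, q, "*") / pt
      w_ref <- sweep(1 - PP, 2, q, "*") / (1 - pt)
      q <- unname(colSums(gg * w_alt) + colSums((2 - gg) * w_ref)) / (2 * M)
      q <- q / sum(q)  # guard against numerical drift off the simplex
    }
    out <- tibble::tibble(sample_id = id)
    for (k in seq_len(K)) out[[paste0("q_", panel_names[k])]] <- q[k]
    out$loglik <- ll
    out$n_sites <- M
    out$n_informative <- sum(informative & obs)
    out$converged <- converged
    if (trace) attr(out, "ll_trace") <- ll_trace
    out
  })
  traces <- if (trace) lapply(rows, attr, "ll_trace") else NULL
  res <- dplyr::bind_rows(rows)
  if (trace) attr(res, "ll_trace") <- stats::setNames(traces, samples)
  if (any(res$n_informative < min_informative)) {
    warning(sum(res$n_informative < min_informative),
            " sample(s) below the informative-site floor", call. = FALSE)
  }
  class(res) <- c("ancestry_q", class(res))
  res
}

#' Birth-year cohort summary of ancestry proportions
#'
#' Bins samples into consecutive fixed-width birth-year classes starting at
#' the earliest birth year (width 3 by default, so a run starting in 1895
#' puts birth year 1903 into the 1901-1903 class), summarises one ancestry
#' component per cohort, and tests for differences across cohorts with the
#' Kruskal-Wallis/Dunn machinery. Cohorts with fewer than 2 samples appear
#' in the table but are excluded from the test and flagged.
#'
#' @param estimates An `ancestry_q` tibble from [fit_q()].
#' @param meta Metadata with `sample_id` and `birth_year`.
#' @param component Name of the ancestry column to summarise (e.g.
#'   `"q_NCC"` for the coastal component).
#' @param class_width_years Cohort width in years (default 3).
#' @return A list of class `cohort_ancestry`: `cohorts` (tibble: `cohort`,
#'   `n`, `mean_q`, `sd_q`, `tested`), `test` (a [kruskal_dunn()] result, or
#'   `NULL` if fewer than 2 testable cohorts) and `component`.
#' @export
cohort_summary <- function(estimates, meta, component,
                           class_width_years = 3) {
  stopifnot(component %in% names(estimates))
  df <- dplyr::inner_join(estimates, meta[, c("sample_id", "birth_year")],
                          by = "sample_id")
  if (!nrow(df) || all(is.na(df$birth_year))) {
    stop("no birth years available", call. = FALSE)
  }
  y0 <- min(df$birth_year, na.rm = TRUE)
  idx <- (df$birth_year - y0) %/% class_width_years
  lo <- y0 + idx * class_width_years
  df$cohort <- sprintf("%d-%d", lo, lo + class_width_years - 1)
  df$q <- df[[component]]
  cohorts <- dplyr::summarise(
    dplyr::group_by(df, .data$cohort),
    n = dplyr::n(),
    mean_q = mean(.data$q), sd_q = stats::sd(.data$q),
    .groups = "drop")
  cohorts$tested <- cohorts$n >= 2
  testable <- df$cohort %in% cohorts$cohort[cohorts$tested]
  test <- if (length(unique(df$cohort[testable])) >= 2) {
    kruskal_dunn(df[testable, ], q, cohort)
  } else {
    NULL
  }
  structure(list(cohorts = dplyr::arrange(cohorts, .data$cohort),
                 test = test, component = component),
            class = "cohort_ancestry")
}

#' @export
print.cohort_ancestry <- function(x, ...) {
  cat(sprintf("<cohort_ancestry> component %s over %d cohorts\n",
              x$component, nrow(x$cohorts)))
  print(x$cohorts)
  if (!is.null(x$test)) {
    cat(sprintf("  Kruskal-Wallis H = %.3f, p = %.4g\n", x$test$h, x$test$p))
  }
  invisible(x)
}

#' Plot per-cohort ancestry proportions
#'
#' @param object A `cohort_ancestry` from [cohort_summary()].
#' @param ... Unused.
#' @return A ggplot object: mean with one standard deviation per cohort.
#' @export
autoplot.cohort_ancestry <- function(object, ...) {
  df <- object$cohorts
  ggplot2::ggplot(df, ggplot2::aes(.data$cohort, .data$mean_q)) +
    ggplot2::geom_col(fill = "#7b6ca8") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_q - .data$sd_q,
                                        ymax = .data$mean_q + .data$sd_q),
                           width = 0.3) +
    ggplot2::labs(x = "birth-year cohort", y = object$component) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
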