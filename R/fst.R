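#' Per-site Weir-Cockerham variance components and FST
#'
#' Two-population Weir-Cockerham estimator computed from genotype counts,
#' including the observed-heterozygosity term. Per site the components
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals) are returned together with
#' `theta = a / (a + b + c)`. Sites monomorphic in the pooled sample (or
#' with an undefined denominator) are excluded and counted in the
#' `"n_excluded"` attribute. Negative estimates are reported as-is.
#'
#' @param gm A [geno] object.
#' @param group_a,group_b Character vectors of sample ids (>= 2 each).
#' @return Tibble with `chrom`, `pos`, `a`, `b`, `c`, `theta`.
#' @export
site_fst <- function(gm, group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  comp <- wc_components(gm$dosage[match(group_a, gm$samples), , drop = FALSE],
                        gm$dosage[match(group_b, gm$samples), , drop = FALSE])
  out <- dplyr::bind_cols(gm$sites[, c("chrom", "pos")], comp)
  keep <- !is.na(out$theta)
  n_excl <- sum(!keep)
  out <- out[keep, ]
  attr(out, "n_excluded") <- n_excl
  out
}

# vectorized Weir & Cockerham (1984) two-population components per site
wc_components <- function(da, db) {
  stats_of <- function(d) {
    n <- unname(colSums(!is.na(d)))
    list(n = n,
         p = ifelse(n > 0, unname(colSums(d, na.rm = TRUE)) / (2 * n), NA_real_),
         h = ifelse(n > 0, unname(colSums(d == 1L, na.rm = TRUE)) / n, NA_real_))
  }
  sa <- stats_of(da); sb <- stats_of(db)
  r <- 2
  n_bar <- (sa$n + sb$n) / r
  n_c <- (r * n_bar - (sa$n^2 + sb$n^2) / (r * n_bar)) / (r - 1)
  p_bar <- (sa$n * sa$p + sb$n * sb$p) / (r * n_bar)
  s2 <- (sa$n * (sa$p - p_bar)^2 + sb$n * (sb$p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (sa$n * sa$h + sb$n * sb$h) / (r * n_bar)
  a <- n_bar / n_c *
    (s2 - 1 / (n_bar - 1) * (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  usable <- !is.na(p_bar) & p_bar > 0 & p_bar < 1 & sa$n >= 2 & sb$n >= 2 &
    !is.na(denom) & denom != 0
  theta <- ifelse(usable, a / denom, NA_real_)
  tibble::tibble(a = ifelse(usable, a, NA_real_),
                 b = ifelse(usable, b, NA_real_),
                 c = ifelse(usable, cc, NA_real_),
                 theta = theta)
}

#' Weighted windowed FST
#'
#' Sliding windows anchored at position 1 of each chromosome; the window
#' estimate is the ratio of sums `sum(a) / sum(a + b + c)` over the sites in
#' the window (the "weighted" estimator), not a mean of per-site ratios.
#' Empty windows are omitted.
#'
#' @param site_components Output of [site_fst()].
#' @param window_bp,step_bp Window and step in bp.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   `n_sites`, `fst`.
#' @export
window_fst <- function(site_components, window_bp = 30000, step_bp = 15000) {
  window_stat(site_components, window_bp, step_bp, function(rows) {
    sum(rows$a) / sum(rows$a + rows$b + rows$c)
  }, value_name = "fst")
}

# shared sliding-window scaffolding: f maps a site-table subset to a scalar
window_stat <- function(site_tbl, window_bp, step_bp, f, value_name = "value",
                        chrom_ends = NULL) {
  pieces <- lapply(split(site_tbl, site_tbl$chrom), function(tb) {
    chrom <- tb$chrom[1]
    end_bp <- if (!is.null(chrom_ends) && chrom %in% names(chrom_ends)) {
      chrom_ends[[chrom]]
    } else {
      max(tb$pos)
    }
    starts <- seq(1L, max(1L, end_bp), by = step_bp)
    res <- lapply(starts, function(s) {
      e <- s + window_bp - 1
      rows <- tb[tb$pos >= s & tb$pos <= e, ]
      if (nrow(rows) == 0) return(NULL)
      tibble::tibble(chrom = chrom, start = s, end = e,
                     n_sites = nrow(rows), value = f(rows))
    })
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(pieces)
  names(out)[names(out) == "value"] <- value_name
  out
}

#' Permutation p-values and per-chromosome q-values for windowed FST
#'
#' Builds a null distribution per chromosome by permuting the group labels
#' across samples `n_perm` times and recomputing the windowed statistic;
#' the empirical p-value per window uses the plus-one rule
#' `p = (1 + #[null >= observed]) / (n_perm + 1)`. q-values are
#' Benjamini-Hochberg within chromosome (a conservative stand-in for
#' Storey's estimator). Deterministic under `seed`.
#'
#' @param windows Output of [window_fst()].
#' @param gm The [geno] object the windows came from.
#' @param group_a,group_b The original group sample ids.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param window_bp,step_bp Must match the observed windows.
#' @return `windows` with columns `p` and `q` added.
#' @export
permutation_q <- function(windows, gm, group_a, group_b, n_perm = 1000,
                          seed = 1L, window_bp = 30000, step_bp = 15000) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  pool <- c(group_a, group_b)
  n_a <- length(group_a)
  if (n_a < 2 || length(group_b) < 2) {
    stop("groups must have at least 2 samples", call. = FALSE)
  }
  # precompute the site membership of every observed window
  key <- paste(windows$chrom, windows$start)
  site_win <- lapply(seq_len(nrow(windows)), function(w) {
    which(gm$sites$chrom == windows$chrom[w] &
            gm$sites$pos >= windows$start[w] &
            gm$sites$pos <= windows$end[w])
  })
  site_idx <- unlist(site_win)
  win_idx <- rep(seq_len(nrow(windows)), lengths(site_win))
  rows_pool <- match(pool, gm$samples)
  exceed <- integer(nrow(windows))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample(rows_pool)
      comp <- wc_components(gm$dosage[idx[seq_len(n_a)], , drop = FALSE],
                            gm$dosage[idx[-seq_len(n_a)], , drop = FALSE])
      a <- comp$a; tot <- comp$a + comp$b + comp$c
      a[is.na(a)] <- 0; tot[is.na(tot)] <- 0  # excluded sites contribute 0
      num <- den <- numeric(nrow(windows))
      rs_a <- rowsum(a[site_idx], win_idx)
      rs_t <- rowsum(tot[site_idx], win_idx)
      num[as.integer(rownames(rs_a))] <- rs_a[, 1]
      den[as.integer(rownames(rs_t))] <- rs_t[, 1]
      null_val <- ifelse(den != 0, num / den, NA_real_)
      exceed <- exceed + as.integer(!is.na(null_val) & null_val >= windows$fst)
    }
  })
  windows$p <- (1 + exceed) / (n_perm + 1)
  windows$q <- stats::ave(windows$p, windows$chrom,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  windows
}

#' Absolute allele-frequency difference per site
#'
#' @param gm A [geno] object.
#' @param group_a,group_b Character vectors of sample ids.
#' @param quantile Genome-wide AFD quantile above which a site is flagged an
#'   outlier (default 0.999).
#' @return Tibble with `chrom`, `pos`, `afd`, `outlier`; the quantile
#'   threshold is attached as attribute `"threshold"`.
#' @export
afd <- function(gm, group_a, group_b, quantile = 0.999) {
  fa <- allele_frequencies(gm, group_a)
  fb <- allele_frequencies(gm, group_b)
  d <- abs(fa$freq - fb$freq)
  thr <- stats::quantile(d, quantile, na.rm = TRUE, names = FALSE)
  out <- dplyr::bind_cols(gm$sites[, c("chrom", "pos")],
                          tibble::tibble(afd = d,
                                         outlier = !is.na(d) & d >= thr))
  attr(out, "threshold") <- thr
  out
}

#' Sites recurrently outlying across comparisons
#'
#' Intersects per-comparison outlier sets and reports sites flagged in at
#' least `min_comparisons` of them, with the list of supporting comparisons.
#'
#' @param outlier_sets Named list of data frames, each with `chrom` and
#'   `pos` rows of the outliers of one comparison.
#' @param min_comparisons Minimum number of supporting comparisons.
#' @return Tibble with `chrom`, `pos`, `n_comparisons`, `comparisons`
#'   (comma-separated names).
#' @export
shared_outliers <- function(outlier_sets, min_comparisons = 2) {
  if (length(outlier_sets) < 2) {
    stop("need at least 2 comparisons", call. = FALSE)
  }
  if (is.null(names(outlier_sets))) {
    names(outlier_sets) <- paste0("comparison_", seq_along(outlier_sets))
  }
  tagged <- purrr::imap(outlier_sets, function(df, nm) {
    tibble::tibble(chrom = df$chrom, pos = df$pos, comparison = nm)
  })
  all <- dplyr::bind_rows(tagged)
  all <- dplyr::distinct(all)
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$chrom, .data$pos),
    n_comparisons = dplyr::n(),
    comparisons = paste(sort(.data$comparison), collapse = ","),
    .groups = "drop")
  dplyr::arrange(out[out$n_comparisons >= min_comparisons, ],
                 .data$chrom, .data$pos)
}

#' Manhattan-style plot of a windowed statistic
#'
#' @param windows A window table with `chrom`, `start`, `end` and a
#'   statistic column.
#' @param stat Name of the statistic column (default: last column).
#' @param regions Optional regions (`chrom`, `start`, `end`) to shade, e.g.
#'   inversions.
#' @return A ggplot object, faceted by chromosome.
#' @export
plot_windows <- function(windows, stat = NULL, regions = NULL) {
  if (is.null(stat)) stat <- setdiff(names(windows),
                                     c("chrom", "start", "end", "n_sites",
                                       "p", "q", "low_confidence"))[1]
  windows$mid <- (windows$start + windows$end) / 2
  p <- ggplot2::ggplot(windows, ggplot2::aes(.data$mid, .data[[stat]]))
  if (!is.null(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "lightblue", alpha = 0.4,
      inherit.aes = FALSE)
  }
  p + ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = stat) +
    ggplot2::theme_minimal()
}
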