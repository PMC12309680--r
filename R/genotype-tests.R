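#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' Estimates the allele frequency from the genotype counts, forms the
#' expected counts `n * (p^2, 2pq, q^2)` and computes the 1-df chi-square.
#' Monomorphic groups return a zero statistic. Groups with any expected
#' cell below 5 are flagged (the asymptotic may be poor).
#'
#' @param counts Integer vector of length 3: counts of the two homozygote
#'   classes flanking the heterozygote, e.g. `c(AA, Aa, aa)` or
#'   `c(ANCESTRAL, HET, DERIVED)`.
#' @return One-row tibble: `chisq`, `p`, `in_hwe` (at 0.05), `small_expected`.
#' @export
#' @examples
#' hwe_chisq(c(25, 50, 25))  # exact HWE: chisq = 0
#' hwe_chisq(c(50, 0, 50))   # no heterozygotes: chisq = 100
hwe_chisq <- function(counts) {
  stopifnot(length(counts) == 3)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("total count is zero", call. = FALSE)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) {
    return(tibble::tibble(chisq = 0, p = 1, in_hwe = TRUE,
                          small_expected = FALSE))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((counts - expected)^2 / expected)
  tibble::tibble(chisq = chisq,
                 p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 in_hwe = stats::pchisq(chisq, df = 1, lower.tail = FALSE) >= 0.05,
                 small_expected = any(expected < 5))
}

#' Genotype-class frequency table by group
#'
#' Tabulates karyotype (or diplotype) calls per group — typically catch year
#' within one population — into counts and within-group frequencies over
#' non-missing calls.
#'
#' @param calls Data frame with `sample_id` and a call column.
#' @param meta Metadata with `sample_id` and the grouping column.
#' @param by Name of the grouping column in `meta` (default `"catch_year"`).
#' @param call_col Name of the call column in `calls` (default `"call"`).
#' @return Tibble with `group`, `class`, `n`, `freq`.
#' @export
genotype_freq_table <- function(calls, meta, by = "catch_year",
                                call_col = "call") {
  df <- dplyr::inner_join(calls, meta[, c("sample_id", by)], by = "sample_id")
  df <- df[!is.na(df[[call_col]]), ]
  out <- dplyr::count(df, group = .data[[by]], class = .data[[call_col]],
                      name = "n")
  out <- dplyr::mutate(dplyr::group_by(out, .data$group),
                       freq = .data$n / sum(.data$n))
  dplyr::ungroup(out)
}

#' Fisher exact tests of genotype frequencies across groups
#'
#' Tests homogeneity of genotype-class frequencies across groups (years):
#' an overall k-by-c exact test (full enumeration where feasible, otherwise
#' Monte Carlo over tables with fixed margins, `>= 1e5` draws under a fixed
#' seed) plus all pairwise group tests with Bonferroni adjustment, from
#' which a compact letter display is built by the insert-and-absorb greedy:
#' groups sharing a letter are not significantly different pairwise.
#'
#' @param freq_table Output of [genotype_freq_table()] (or any tibble with
#'   `group`, `class`, `n`).
#' @param alpha Significance level for the letter display.
#' @param mc_draws Monte-Carlo table draws when enumeration is infeasible.
#' @param seed Seed for the Monte-Carlo test.
#' @return A list of class `fisher_years` with `overall_p`, `pairwise`
#'   (tibble: `group1`, `group2`, `p`, `p_adjusted`), `letters` (tibble:
#'   `group`, `letters`) and `alpha`.
#' @export
fisher_years <- function(freq_table, alpha = 0.05, mc_draws = 1e5, seed = 1L) {
  tab <- tidyr::pivot_wider(freq_table[, c("group", "class", "n")],
                            names_from = "class", values_from = "n",
                            values_fill = 0L)
  groups <- as.character(tab$group)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- groups
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning("dropping empty group(s): ", paste(groups[empty], collapse = ", "),
            call. = FALSE)
    m <- m[!empty, , drop = FALSE]
    groups <- groups[!empty]
  }
  if (nrow(m) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  overall_p <- withr::with_seed(seed, exact_or_mc_fisher(m, mc_draws))

  pairs <- utils::combn(seq_along(groups), 2)
  pw <- purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    sub <- m[c(i1, i2), , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    p <- if (ncol(sub) < 2) 1 else {
      withr::with_seed(seed + j, exact_or_mc_fisher(sub, mc_draws))
    }
    tibble::tibble(group1 = groups[i1], group2 = groups[i2], p = p)
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adjusted <- pmin(1, pw$p * nrow(pw))  # Bonferroni

  sig <- matrix(FALSE, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (j in seq_len(nrow(pw))) {
    s <- pw$p_adjusted[j] < alpha
    sig[pw$group1[j], pw$group2[j]] <- s
    sig[pw$group2[j], pw$group1[j]] <- s
  }
  structure(list(overall_p = overall_p, pairwise = pw,
                 letters = compact_letters(sig), alpha = alpha),
            class = "fisher_years")
}

exact_or_mc_fisher <- function(m, mc_draws) {
  res <- tryCatch(stats::fisher.test(m), error = function(e) NULL)
  if (is.null(res)) {
    res <- stats::fisher.test(m, simulate.p.value = TRUE, B = mc_draws)
  }
  unname(res$p.value)
}

# Piepho-style insert-and-absorb compact letter display from a logical
# significance matrix (TRUE = significantly different)
compact_letters <- function(sig) {
  groups <- rownames(sig)
  sets <- list(groups)  # start: one letter containing everybody
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i || !sig[i, j]) next
      for (s in seq_along(sets)) {
        if (all(c(groups[i], groups[j]) %in% sets[[s]])) {
          # duplicate the offending letter, removing one group from each copy
          a <- setdiff(sets[[s]], groups[i])
          b <- setdiff(sets[[s]], groups[j])
          sets[[s]] <- a
          sets[[length(sets) + 1]] <- b
        }
      }
      # absorb sets wholly contained in another
      keep <- rep(TRUE, length(sets))
      for (s in seq_along(sets)) {
        for (t in seq_along(sets)) {
          if (s != t && keep[t] && all(sets[[s]] %in% sets[[t]]) &&
              (length(sets[[s]]) < length(sets[[t]]) || s > t)) {
            keep[s] <- FALSE
            break
          }
        }
      }
      sets <- sets[keep]
    }
  }
  labels <- vapply(groups, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, TRUE))],
          collapse = "")
  }, "")
  tibble::tibble(group = groups, letters = unname(labels))
}

#' @export
print.fisher_years <- function(x, ...) {
  cat(sprintf("<fisher_years> overall p = %.4g (alpha = %g)\n",
              x$overall_p, x$alpha))
  print(x$letters)
  invisible(x)
}

#' @rdname fisher_years
#' @param x A `fisher_years` object.
#' @param ... Unused.
#' @export
tidy.fisher_years <- function(x, ...) x$pairwise

#' @rdname fisher_years
#' @export
glance.fisher_years <- function(x, ...) {
  tibble::tibble(overall_p = x$overall_p,
                 n_groups = nrow(x$letters),
                 n_significant_pairs = sum(x$pairwise$p_adjusted < x$alpha))
}

#' Two-site diplotype classification
#'
#' Combines the genotype calls at two codon SNPs (e.g. the two
#' nonsynonymous hemoglobin beta-1 substitutions at codons 55 and 62) into
#' the diplotype classes homozygous-reference at both, double heterozygote,
#' homozygous-alternate at both, or `other` for discordant combinations.
#' Allele polarization (which homozygote class is the cold-water Val-Ala)
#' is supplied through the class labels, not hard-coded coordinates.
#'
#' @param gm A [geno] object.
#' @param site1,site2 Each a list or one-row data frame with `chrom`, `pos`.
#' @param labels Length-3 class names for (hom-ref/hom-ref, double-het,
#'   hom-alt/hom-alt); default the hemoglobin convention with ref polarized
#'   to Val/Ala.
#' @return Tibble with `sample_id`, `class` (`NA` if either genotype is
#'   missing).
#' @export
hb_diplotype <- function(gm, site1, site2,
                         labels = c("Val-Ala", "HET-HET", "Met-Lys")) {
  find_site <- function(s) {
    i <- which(gm$sites$chrom == s$chrom & gm$sites$pos == s$pos)
    if (length(i) != 1) stop("site ", s$chrom, ":", s$pos, " not found",
                             call. = FALSE)
    i
  }
  d1 <- gm$dosage[, find_site(site1)]
  d2 <- gm$dosage[, find_site(site2)]
  cls <- dplyr::case_when(
    is.na(d1) | is.na(d2) ~ NA_character_,
    d1 == 0L & d2 == 0L ~ labels[1],
    d1 == 1L & d2 == 1L ~ labels[2],
    d1 == 2L & d2 == 2L ~ labels[3],
    TRUE ~ "other"
  )
  tibble::tibble(sample_id = gm$samples, class = cls)
}

#' Kruskal-Wallis rank test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H test for stochastic dominance among
#' groups, followed by all pairwise Dunn z tests (tie-corrected) with
#' Benjamini-Hochberg adjustment across pairs.
#'
#' @param data A data frame.
#' @param value,group Column names (strings or bare names via `{{ }}`) of
#'   the response values and the grouping variable.
#' @return A list of class `kruskal_dunn`: `h`, `df`, `p`, `pairwise`
#'   (tibble: `group1`, `group2`, `z`, `p`, `p_adjusted`), `n`.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 3), v = c(1, 2, 3, 10, 11, 12))
#' kruskal_dunn(df, v, g)
kruskal_dunn <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  sizes <- table(g)
  if (any(sizes == 0)) warning("dropping empty group(s)", call. = FALSE)
  if (length(sizes) < 2 || length(v) < 2) {
    stop("need at least 2 groups and 2 values", call. = FALSE)
  }
  n <- length(v)
  rk <- rank(v)
  ties <- table(rk)
  tie_sum <- sum(ties^3 - ties)
  rbar <- tapply(rk, g, mean)
  ni <- as.numeric(table(g)[names(rbar)])
  h_raw <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  tie_corr <- 1 - tie_sum / (n^3 - n)
  if (tie_corr <= 0) {
    h <- 0; p <- 1  # every value identical
  } else {
    h <- h_raw / tie_corr
    p <- stats::pchisq(h, df = length(ni) - 1, lower.tail = FALSE)
  }
  # Dunn's pairwise z with tie correction
  sigma2 <- (n * (n + 1) / 12) - tie_sum / (12 * (n - 1))
  grp <- names(rbar)
  pairs <- utils::combn(seq_along(grp), 2)
  pw <- purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(sigma2 * (1 / ni[i1] + 1 / ni[i2]))
    z <- if (se > 0) (rbar[[i1]] - rbar[[i2]]) / se else 0
    tibble::tibble(group1 = grp[i1], group2 = grp[i2], z = z,
                   p = 2 * stats::pnorm(-abs(z)))
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adjusted <- stats::p.adjust(pw$p, "BH")
  structure(list(h = h, df = length(ni) - 1, p = p, pairwise = pw, n = n),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("<kruskal_dunn> H = %.3f, df = %d, p = %.4g (n = %d)\n",
              x$h, x$df, x$p, x$n))
  invisible(x)
}

#' @rdname kruskal_dunn
#' @param x A `kruskal_dunn` object.
#' @param ... Unused.
#' @export
tidy.kruskal_dunn <- function(x, ...) x$pairwise

#' @rdname kruskal_dunn
#' @export
glance.kruskal_dunn <- function(x, ...) {
  tibble::tibble(h = x$h, df = x$df, p = x$p, n = x$n)
}
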