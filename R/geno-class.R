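#' Genotype matrix container
#'
#' A `geno` object holds a diploid dosage matrix (samples in rows, biallelic
#' sites in columns, values 0/1/2 counting copies of the alternate allele,
#' `NA` for missing), a site table and the sample ids. It is the substrate of
#' every analysis stage in tempogen.
#'
#' @param dosage Integer matrix, samples x sites, values in `{0, 1, 2, NA}`.
#' @param sites A data frame with one row per site and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`.
#' @param samples Character vector of sample ids, one per row of `dosage`.
#'
#' @return An object of class `geno`.
#' @export
#' @examples
#' g <- geno(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'           sites = data.frame(chrom = "LG01", pos = c(100L, 200L),
#'                              ref = "A", alt = "C"),
#'           samples = c("s1", "s2"))
#' g
geno <- function(dosage, sites, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  sites <- tibble::as_tibble(sites)
  stopifnot(
    nrow(dosage) == length(samples),
    ncol(dosage) == nrow(sites),
    all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    !anyDuplicated(samples)
  )
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  # positions strictly increasing within chromosome
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    dosage <- dosage[, ord, drop = FALSE]
    sites <- sites[ord, ]
  }
  if (any(stats::ave(sites$pos, sites$chrom, FUN = function(p) c(1, diff(p))) <= 0)) {
    stop("site positions must be strictly increasing within each chromosome",
         call. = FALSE)
  }
  rownames(dosage) <- samples
  colnames(dosage) <- paste0(sites$chrom, ":", sites$pos)
  structure(list(dosage = dosage, sites = sites, samples = as.character(samples)),
            class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf("<geno> %d samples x %d sites (%.1f%% missing)\n",
              n_samples(x), n_sites(x), 100 * miss))
  chr <- table(x$sites$chrom)
  cat("  chromosomes:", paste0(names(chr), " (", chr, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Dimensions of a geno object
#' @param g A [geno] object.
#' @return Integer scalar.
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_sites <- function(g) ncol(g$dosage)

#' Subset a geno object
#'
#' @param x A [geno] object.
#' @param i Sample selector: character ids or logical/integer index.
#' @param j Site selector: logical or integer index into the site table.
#' @param ... Unused.
#' @param drop Ignored; subsetting always returns a `geno`.
#' @return A [geno] object.
#' @export
`[.geno` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_sites(x))
  if (is.character(i)) {
    idx <- match(i, x$samples)
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(i[is.na(idx)], collapse = ", "), call. = FALSE)
    i <- idx
  }
  geno(x$dosage[i, j, drop = FALSE], x$sites[j, , drop = FALSE], x$samples[i])
}

#' Site and sample tables of a geno object
#'
#' @param g A [geno] object.
#' @return `sites()` returns the site tibble; `samples()` the sample id vector.
#' @export
sites <- function(g) g$sites

#' @rdname sites
#' @export
sample_ids <- function(g) g$samples

#' Long-format view of a genotype matrix
#'
#' @param x A [geno] object.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `dosage`.
#' @export
as_tibble.geno <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$samples, times = n_sites(x)),
    chrom = rep(x$sites$chrom, each = n_samples(x)),
    pos = rep(x$sites$pos, each = n_samples(x)),
    dosage = as.integer(x$dosage)
  )
}

keep_sites <- function(g, keep) {
  g$dosage <- g$dosage[, keep, drop = FALSE]
  g$sites <- g$sites[keep, , drop = FALSE]
  g
}
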