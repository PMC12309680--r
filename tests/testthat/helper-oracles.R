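# Fixture builders and independent brute-force oracles used across the suite.
# The oracles are deliberately scalar, loop-based transcriptions of the
# published formulas, kept independent of the vectorized implementations.

make_geno <- function(dosage, chrom = "LG01", pos = NULL,
                      ref = "A", alt = "C", samples = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); L <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(L) * 100L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n))
  geno(dosage,
       tibble::tibble(chrom = rep_len(chrom, L), pos = as.integer(pos),
                      ref = rep_len(ref, L), alt = rep_len(alt, L)),
       samples)
}

random_geno <- function(n, L, miss = 0, chrom = "LG01", pos = NULL) {
  p <- runif(L, 0.05, 0.95)
  d <- vapply(p, function(pp) rbinom(n, 2, pp), integer(n))
  if (miss > 0) d[runif(length(d)) < miss] <- NA_integer_
  make_geno(d, chrom = chrom, pos = pos)
}

# --- Weir & Cockerham (1984) two-population components, scalar form -------
oracle_wc_site <- function(dos_a, dos_b) {
  count <- function(d) {
    d <- d[!is.na(d)]
    n <- length(d)
    list(n = n, p = sum(d) / (2 * n), h = sum(d == 1) / n)
  }
  A <- count(dos_a); B <- count(dos_b)
  r <- 2
  nbar <- (A$n + B$n) / r
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# --- Tajima (1989) D for one window, scalar transcription ------------------
# freqs: alt-allele frequencies; n_alleles: per-site observed allele counts
oracle_tajima_d <- function(freqs, n_alleles) {
  seg <- freqs > 0 & freqs < 1
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  theta_pi <- 0
  for (i in which(seg)) {
    ni <- n_alleles[i]
    theta_pi <- theta_pi + 2 * freqs[i] * (1 - freqs[i]) * ni / (ni - 1)
  }
  n <- round(length(n_alleles) / sum(1 / n_alleles))
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_pi <- function(freqs, n_alleles, window_bp) {
  tot <- 0
  for (i in seq_along(freqs)) {
    ni <- n_alleles[i]
    tot <- tot + 2 * freqs[i] * (1 - freqs[i]) * ni / (ni - 1)
  }
  tot / window_bp
}

# per-sample dosage draw from HWE at frequency p, plan II sample of size n
hwe_sample <- function(n, p) rbinom(n, 2, p)
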