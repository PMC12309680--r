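#' Forward Wright-Fisher simulation of two interbreeding ecotypes
#'
#' Simulates a migratory and a coastal population forward in time under
#' drift, time-varying directional gene flow, and optional viability
#' selection on inversion karyotypes, then draws temporally distributed
#' samples per the sampling schedule.
#'
#' Neutral loci evolve at the allele-frequency level: one ancestral Beta
#' frequency per SNP, independent burn-in drift per population (creating the
#' weak genome-wide background differentiation), then, each generation,
#' deterministic migration mixing of the gene pools followed by binomial
#' resampling of `2N` allele copies. Each inversion is a single Mendelian
#' biallelic arrangement locus transmitted without recombination; selection
#' acts as karyotype viability weights before parent sampling. Sampled
#' individuals are instantiated only at their birth generation, with
#' genotypes drawn from Hardy-Weinberg proportions at the then-current
#' frequencies; their true coastal-ancestry fraction is tracked through an
#' explicit short pedigree (migrant parents drawn per the migration rate of
#' each generation). Sampling follows plan II: sampled fish are caught
#' before reproducing and contribute nothing to later generations (at desk
#' scale, samples are far smaller than the census, so removal does not
#' perturb the frequencies).
#'
#' @param config A [sim_config()].
#' @return A list of class `cohort_sim` with elements
#'   * `geno`: a [geno] object for all sampled individuals (fully observed;
#'     see [inject_missingness()] for historical-sample degradation),
#'   * `samples`: tibble with `sample_id`, `population`, `ecotype`,
#'     `catch_year`, `birth_year`, `age`,
#'   * `truth`: ground truth for recovery tests — per-sample karyotypes per
#'     inversion, per-sample coastal-ancestry fractions, per-generation
#'     allele/arrangement frequencies, and any fixation warnings,
#'   * `config`: the input configuration.
#' @export
#' @examples
#' cfg <- sim_config(n_neutral_snps = 100, n_chromosomes = 2,
#'                   inversions = list(), n_migratory = 100, n_coastal = 100,
#'                   sampling = data.frame(year = c(1907, 2014),
#'                                         population = "migratory", n = 10))
#' sim <- simulate_cohorts(cfg)
#' sim$geno
simulate_cohorts <- function(config) {
  cfg <- validate_sim_config(config)
  withr::with_seed(cfg$seed, simulate_cohorts_impl(cfg))
}

simulate_cohorts_impl <- function(cfg) {
  G <- cfg$n_generations
  n_inv <- length(cfg$inversions)
  warnings <- character()

  sites <- build_site_table(cfg)
  neutral_idx <- which(sites$kind == "neutral")
  L <- length(neutral_idx)   # realized count after dedup/inversion exclusion

  # --- ancestral frequencies and per-population burn-in drift -------------
  p_anc <- stats::rbeta(L, cfg$divergence_beta[1], cfg$divergence_beta[2])
  p_mig <- drift_generations(p_anc, cfg$n_migratory, cfg$burn_in_generations)
  p_cst <- drift_generations(p_anc, cfg$n_coastal, cfg$burn_in_generations)

  # --- calendar-time recursion --------------------------------------------
  freq_mig <- matrix(NA_real_, L, G + 1)
  freq_cst <- matrix(NA_real_, L, G + 1)
  freq_mig[, 1] <- p_mig; freq_cst[, 1] <- p_cst
  q_mig <- vapply(cfg$inversions, `[[`, 0, "init_freq_migratory")
  q_cst <- vapply(cfg$inversions, `[[`, 0, "init_freq_coastal")
  inv_freq_mig <- matrix(NA_real_, n_inv, G + 1)
  inv_freq_cst <- matrix(NA_real_, n_inv, G + 1)
  if (n_inv) { inv_freq_mig[, 1] <- q_mig; inv_freq_cst[, 1] <- q_cst }
  anc_mig <- numeric(G + 1); anc_cst <- numeric(G + 1)
  anc_mig[1] <- 0; anc_cst[1] <- 1
  m_cm_hist <- numeric(G); m_mc_hist <- numeric(G)

  for (g in seq_len(G)) {
    yr <- generation_to_year(g, cfg)
    m <- migration_at(cfg, yr)
    m_cm_hist[g] <- m["m_cm"]; m_mc_hist[g] <- m["m_mc"]

    # migration as deterministic frequency mixing before reproduction
    pm <- (1 - m["m_cm"]) * freq_mig[, g] + m["m_cm"] * freq_cst[, g]
    pc <- (1 - m["m_mc"]) * freq_cst[, g] + m["m_mc"] * freq_mig[, g]
    freq_mig[, g + 1] <- drift_generations(pm, cfg$n_migratory, 1)
    freq_cst[, g + 1] <- drift_generations(pc, cfg$n_coastal, 1)

    anc_mig[g + 1] <- (1 - m["m_cm"]) * anc_mig[g] + m["m_cm"] * anc_cst[g]
    anc_cst[g + 1] <- (1 - m["m_mc"]) * anc_cst[g] + m["m_mc"] * anc_mig[g]

    if (n_inv) {
      qm <- (1 - m["m_cm"]) * inv_freq_mig[, g] + m["m_cm"] * inv_freq_cst[, g]
      qc <- (1 - m["m_mc"]) * inv_freq_cst[, g] + m["m_mc"] * inv_freq_mig[, g]
      for (k in seq_len(n_inv)) {
        w <- selection_at(cfg, yr, cfg$inversions[[k]]$id)
        qm[k] <- select_viability(qm[k], w)
        qc[k] <- select_viability(qc[k], w)
      }
      inv_freq_mig[, g + 1] <- stats::rbinom(n_inv, 2 * cfg$n_migratory, qm) /
        (2 * cfg$n_migratory)
      inv_freq_cst[, g + 1] <- stats::rbinom(n_inv, 2 * cfg$n_coastal, qc) /
        (2 * cfg$n_coastal)
      fixed <- inv_freq_mig[, g + 1] %in% c(0, 1) & !(inv_freq_mig[, g] %in% c(0, 1))
      if (any(fixed)) {
        w_msg <- sprintf("inversion %s lost/fixed in migratory population at generation %d",
                         vapply(cfg$inversions[fixed], `[[`, "", "id"), g)
        warnings <- c(warnings, w_msg)
        warning(paste(w_msg, collapse = "; "), call. = FALSE)
      }
    }
  }

  # --- instantiate sampled individuals ------------------------------------
  sam <- draw_sample_table(cfg)
  n_tot <- nrow(sam)
  dosage <- matrix(NA_integer_, n_tot, nrow(sites))
  anc_true <- numeric(n_tot)
  kary <- if (n_inv) matrix(NA_integer_, n_tot, n_inv) else NULL
  ped_depth <- ceiling(cfg$age_range[2] / cfg$generation_time_years) + 1

  for (i in seq_len(n_tot)) {
    gb <- max(0L, min(G, year_to_generation(sam$birth_year[i], cfg)))
    mig <- sam$ecotype[i] == "migratory"
    pfreq <- if (mig) freq_mig[, gb + 1] else freq_cst[, gb + 1]
    dosage[i, neutral_idx] <- stats::rbinom(L, 2L, pfreq)
    anc_true[i] <- pedigree_ancestry(gb, ped_depth, mig, m_cm_hist, m_mc_hist,
                                     anc_mig, anc_cst)
    if (n_inv) {
      qv <- if (mig) inv_freq_mig[, gb + 1] else inv_freq_cst[, gb + 1]
      for (k in seq_len(n_inv)) {
        inv <- cfg$inversions[[k]]
        hap <- stats::rbinom(2, 1, qv[k])      # two arrangement alleles
        kary[i, k] <- sum(hap)
        idx <- which(sites$inversion == inv$id)
        tag1 <- ifelse(stats::runif(length(idx)) < inv$tag_fidelity, hap[1], 1 - hap[1])
        tag2 <- ifelse(stats::runif(length(idx)) < inv$tag_fidelity, hap[2], 1 - hap[2])
        dosage[i, idx] <- as.integer(tag1 + tag2)
      }
    }
  }

  gm <- geno(dosage, sites[, c("chrom", "pos", "ref", "alt")], sam$sample_id)
  inv_ids <- vapply(cfg$inversions, `[[`, "", "id")
  truth <- list(
    ancestry = tibble::tibble(sample_id = sam$sample_id,
                              coastal_ancestry = anc_true),
    karyotypes = if (n_inv) tibble::tibble(
      sample_id = rep(sam$sample_id, times = n_inv),
      inversion = rep(inv_ids, each = n_tot),
      n_derived = as.integer(kary),
      karyotype = c("ANCESTRAL", "HET", "DERIVED")[as.integer(kary) + 1L]
    ) else tibble::tibble(sample_id = character(), inversion = character(),
                          n_derived = integer(), karyotype = character()),
    freq_migratory = freq_mig, freq_coastal = freq_cst,
    inversion_freq = if (n_inv) tibble::tibble(
      generation = rep(0:G, each = n_inv),
      inversion = rep(inv_ids, times = G + 1),
      freq_migratory = as.numeric(inv_freq_mig),
      freq_coastal = as.numeric(inv_freq_cst)
    ) else NULL,
    mean_ancestry = tibble::tibble(generation = 0:G,
                                   migratory = anc_mig, coastal = anc_cst),
    warnings = warnings
  )
  structure(list(geno = gm, samples = sam, truth = truth, config = cfg),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d samples, %d sites, %d inversions, years %s\n",
              nrow(x$samples), n_sites(x$geno), length(x$config$inversions),
              paste(sort(unique(x$samples$catch_year)), collapse = "/")))
  invisible(x)
}

build_site_table <- function(cfg) {
  chroms <- sprintf("LG%02d", seq_len(cfg$n_chromosomes))
  inv_by_chrom <- split(cfg$inversions,
                        vapply(cfg$inversions, `[[`, "", "chrom"))
  per_chrom <- table(factor(sample(chroms, cfg$n_neutral_snps, replace = TRUE),
                            levels = chroms))
  pieces <- list()
  for (ch in chroms) {
    n_ch <- per_chrom[[ch]]
    invs <- inv_by_chrom[[ch]]
    pos <- sort(sample.int(cfg$chromosome_length_bp, n_ch))
    if (!is.null(invs)) {
      for (inv in invs) pos <- pos[pos < inv$start | pos > inv$end]
    }
    if (length(pos)) {
      pieces[[length(pieces) + 1L]] <-
        tibble::tibble(chrom = ch, pos = pos, kind = "neutral",
                       inversion = NA_character_)
    }
    if (!is.null(invs)) {
      for (inv in invs) {
        bp <- sort(sample(inv$start:inv$end, inv$n_block_snps))
        pieces[[length(pieces) + 1L]] <-
          tibble::tibble(chrom = ch, pos = bp, kind = "block",
                         inversion = inv$id)
      }
    }
  }
  sites <- dplyr::arrange(dplyr::bind_rows(pieces), .data$chrom, .data$pos)
  sites <- sites[!duplicated(sites[, c("chrom", "pos")]), ]
  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, nrow(sites), replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(bases, r), 1), "")
  sites
}

drift_generations <- function(p, n_diploid, t) {
  for (g in seq_len(t)) p <- stats::rbinom(length(p), 2 * n_diploid, p) / (2 * n_diploid)
  p
}

migration_at <- function(cfg, year) {
  m <- cfg$migration
  hit <- which(year >= m$year_from & year <= m$year_to)
  if (length(hit)) c(m_cm = m$m_cm[hit[1]], m_mc = m$m_mc[hit[1]])
  else c(m_cm = 0, m_mc = 0)
}

selection_at <- function(cfg, year, inversion_id) {
  s <- cfg$selection
  if (is.null(s)) return(c(1, 1, 1))
  hit <- which(year >= s$year_from & year <= s$year_to & s$inversion == inversion_id)
  if (length(hit)) c(s$w_anc[hit[1]], s$w_het[hit[1]], s$w_der[hit[1]])
  else c(1, 1, 1)
}

# deterministic viability selection on a single biallelic locus;
# q is the DERIVED frequency, w = (w_anc, w_het, w_der)
select_viability <- function(q, w) {
  if (all(w == w[1])) return(q)
  wbar <- (1 - q)^2 * w[1] + 2 * q * (1 - q) * w[2] + q^2 * w[3]
  if (wbar == 0) return(q)
  (q^2 * w[3] + q * (1 - q) * w[2]) / wbar
}

draw_sample_table <- function(cfg) {
  labels <- c(migratory = "NEAC", coastal = "NCC")
  rows <- purrr::pmap(cfg$sampling, function(year, population, n) {
    age <- draw_ages(n, cfg$age_range, cfg$age_geom_p)
    eco <- population
    tibble::tibble(
      population = labels[[eco]],
      ecotype = eco,
      catch_year = as.integer(year),
      age = as.integer(age),
      birth_year = as.integer(year - age)
    )
  })
  sam <- dplyr::bind_rows(rows)
  sam$sample_id <- sprintf("%s_%d_%03d", sam$population, sam$catch_year,
                           as.integer(stats::ave(seq_len(nrow(sam)),
                                                 paste(sam$population, sam$catch_year),
                                                 FUN = seq_along)))
  sam[, c("sample_id", "population", "ecotype", "catch_year", "birth_year", "age")]
}

# truncated geometric age-at-catch distribution on [amin, amax]
draw_ages <- function(n, age_range, p) {
  amin <- age_range[1]; amax <- age_range[2]
  if (amin == amax) return(rep(amin, n))
  support <- amin:amax
  pr <- (1 - p)^(support - amin)
  sample(support, n, replace = TRUE, prob = pr / sum(pr))
}

# true coastal-ancestry fraction of one newborn via a short random pedigree:
# each parent at generation g is a coastal immigrant with the migration
# probability of that generation, otherwise a resident whose ancestry is
# resolved one generation further back (population mean beyond `depth`).
pedigree_ancestry <- function(g, depth, migratory, m_cm, m_mc, anc_mig, anc_cst) {
  if (g <= 0 || depth <= 0) {
    return(if (migratory) anc_mig[g + 1] else anc_cst[g + 1])
  }
  m <- if (migratory) m_cm[g] else m_mc[g]
  parent <- function() {
    if (stats::runif(1) < m) {
      # immigrant parent from the other population, born one generation back
      pedigree_ancestry(g - 1, depth - 1, !migratory, m_cm, m_mc, anc_mig, anc_cst)
    } else {
      pedigree_ancestry(g - 1, depth - 1, migratory, m_cm, m_mc, anc_mig, anc_cst)
    }
  }
  (parent() + parent()) / 2
}
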