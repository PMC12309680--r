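#' Specify an inversion supergene for the simulator
#'
#' An inversion is modelled as a single Mendelian biallelic locus (the
#' arrangement, ANCESTRAL vs DERIVED) transmitted without recombination,
#' plus a block of tightly linked tag SNPs inside the inverted interval.
#' Each block-SNP allele on a haplotype tags the arrangement carried by that
#' haplotype with probability `tag_fidelity` (1 minus the gene-flux error),
#' so `tag_fidelity = 1` means perfect tagging.
#'
#' @param id Inversion identifier, e.g. `"inv_LG01"`.
#' @param chrom Chromosome id.
#' @param start,end 1-based interval of the inversion in bp.
#' @param n_block_snps Number of tag SNPs placed uniformly in `[start, end]`.
#' @param tag_fidelity Probability in (0.5, 1] that a block-SNP allele tags
#'   the arrangement on its haplotype.
#' @param init_freq_migratory,init_freq_coastal Initial DERIVED-arrangement
#'   frequency in the migratory and the coastal population.
#' @return A list of class `inversion_spec`.
#' @export
inversion_spec <- function(id, chrom, start, end, n_block_snps = 150,
                           tag_fidelity = 0.98,
                           init_freq_migratory = 0.9,
                           init_freq_coastal = 0.1) {
  stopifnot(start >= 1, end > start, n_block_snps >= 1,
            tag_fidelity > 0.5, tag_fidelity <= 1,
            init_freq_migratory >= 0, init_freq_migratory <= 1,
            init_freq_coastal >= 0, init_freq_coastal <= 1)
  structure(list(id = id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), n_block_snps = as.integer(n_block_snps),
                 tag_fidelity = tag_fidelity,
                 init_freq_migratory = init_freq_migratory,
                 init_freq_coastal = init_freq_coastal),
            class = "inversion_spec")
}

default_inversions <- function(chrom_len) {
  s <- as.integer(0.25 * chrom_len); e <- as.integer(0.65 * chrom_len)
  list(
    # migratory ecotype dominated by DERIVED on LG01/LG07, ANCESTRAL on LG02/LG12
    inversion_spec("inv_LG01", "LG01", s, e, init_freq_migratory = 0.95,
                   init_freq_coastal = 0.15),
    inversion_spec("inv_LG02", "LG02", s, e, init_freq_migratory = 0.05,
                   init_freq_coastal = 0.85),
    inversion_spec("inv_LG07", "LG07", s, e, init_freq_migratory = 0.95,
                   init_freq_coastal = 0.20),
    inversion_spec("inv_LG12", "LG12", s, e, init_freq_migratory = 0.05,
                   init_freq_coastal = 0.75)
  )
}

default_sampling <- function() {
  tibble::tibble(
    year = c(1907, 1940, 1958, 1975, 1999, 2011, 2014, 2011, 2014),
    population = c(rep("migratory", 7), "coastal", "coastal"),
    n = c(27L, 21L, 15L, 11L, 11L, 22L, 26L, 26L, 25L)
  )
}

default_migration <- function() {
  # directional coastal->migratory gene flow, cyclic over the century with
  # post-millennium intensification; reverse flow weak and constant
  tibble::tibble(
    year_from = c(1880, 1900, 1907, 1996),
    year_to   = c(1899, 1906, 1995, 2014),
    m_cm      = c(0.010, 0.050, 0.010, 0.080),
    m_mc      = c(0.005, 0.005, 0.005, 0.005)
  )
}

#' Build a simulation configuration
#'
#' Defines the stated world of the two-ecotype Wright-Fisher simulator:
#' census sizes, timeline, neutral-SNP architecture, initial divergence,
#' migration and selection schedules, the temporal sampling design and the
#' era-specific missingness of historical samples. Defaults emulate a
#' century-scale study of a migratory ecotype sampled at the spawning ground
#' in 1907, 1940, 1958, 1975, 1999, 2011 and 2014 together with a modern
#' coastal outgroup, four inversion supergenes discriminating the ecotypes,
#' and weak genome-wide background differentiation.
#'
#' @param n_migratory,n_coastal Diploid census sizes.
#' @param year_start First simulated calendar year (generation 0).
#' @param year_end Last calendar year that must be reachable.
#' @param generation_time_years Years per generation; generation `g`
#'   corresponds to `year_start + g * generation_time_years`.
#' @param n_neutral_snps Number of unlinked neutral SNPs outside inversions.
#' @param n_chromosomes Number of chromosomes (`LG01`, `LG02`, ...).
#' @param chromosome_length_bp Length of each chromosome in bp.
#' @param divergence_beta Shape pair of the Beta distribution from which one
#'   ancestral allele frequency per SNP is drawn.
#' @param burn_in_generations Generations of independent drift per population
#'   before the calendar timeline starts; creates the weak background
#'   differentiation between the ecotypes.
#' @param migration A data frame with columns `year_from`, `year_to`,
#'   `m_cm` (per-generation proportion of the migratory gene pool replaced by
#'   coastal migrants) and `m_mc` (the reverse direction).
#' @param inversions List of [inversion_spec()] objects (possibly empty).
#' @param selection A data frame with columns `year_from`, `year_to`,
#'   `inversion`, `w_anc`, `w_het`, `w_der`: relative viabilities of the
#'   ANCESTRAL homokaryotype, the heterokaryotype and the DERIVED
#'   homokaryotype applied before parent sampling. `NULL` for neutrality.
#' @param sampling A data frame with columns `year`, `population`
#'   (`"migratory"` or `"coastal"`) and `n` (diploid individuals caught).
#' @param age_range Two integers: minimum and maximum age (years) at catch.
#' @param age_geom_p Success parameter of the truncated geometric age
#'   distribution on `age_range`.
#' @param missingness A data frame with columns `year_to` (era upper bound on
#'   catch year), `miss_rate` and `error_rate`, used by
#'   [inject_missingness()]; `NULL` for fully observed genotypes.
#' @param seed Integer seed; the simulation is fully deterministic given the
#'   configuration.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_neutral_snps = 200, n_chromosomes = 2, inversions = list())
#' cfg$n_generations
sim_config <- function(n_migratory = 1000,
                       n_coastal = 500,
                       year_start = 1880,
                       year_end = 2014,
                       generation_time_years = 8,
                       n_neutral_snps = 5000,
                       n_chromosomes = 12,
                       chromosome_length_bp = 2e6,
                       divergence_beta = c(0.8, 0.8),
                       burn_in_generations = 40,
                       migration = default_migration(),
                       inversions = default_inversions(chromosome_length_bp),
                       selection = NULL,
                       sampling = default_sampling(),
                       age_range = c(4L, 14L),
                       age_geom_p = 0.25,
                       missingness = tibble::tibble(
                         year_to = c(1999, Inf),
                         miss_rate = c(0.15, 0.02),
                         error_rate = c(0.005, 0.001)),
                       seed = 1L) {
  n_generations <- ceiling((year_end - year_start) / generation_time_years)
  cfg <- list(
    n_migratory = as.integer(n_migratory), n_coastal = as.integer(n_coastal),
    year_start = year_start, year_end = year_end,
    generation_time_years = generation_time_years,
    n_generations = as.integer(n_generations),
    n_neutral_snps = as.integer(n_neutral_snps),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.integer(chromosome_length_bp),
    divergence_beta = divergence_beta,
    burn_in_generations = as.integer(burn_in_generations),
    migration = tibble::as_tibble(migration),
    inversions = inversions,
    selection = if (is.null(selection)) NULL else tibble::as_tibble(selection),
    sampling = tibble::as_tibble(sampling),
    age_range = as.integer(age_range),
    age_geom_p = age_geom_p,
    missingness = if (is.null(missingness)) NULL else tibble::as_tibble(missingness),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_migratory >= 1, cfg$n_coastal >= 1,
            cfg$generation_time_years > 0, cfg$n_generations >= 1,
            cfg$n_neutral_snps >= 0, cfg$n_chromosomes >= 1,
            length(cfg$divergence_beta) == 2, all(cfg$divergence_beta > 0),
            cfg$burn_in_generations >= 0,
            cfg$age_range[1] >= 0, cfg$age_range[2] >= cfg$age_range[1],
            cfg$age_geom_p > 0, cfg$age_geom_p < 1)
  m <- cfg$migration
  if (!all(c(m$m_cm, m$m_mc) >= 0 & c(m$m_cm, m$m_mc) <= 1)) {
    stop("migration rates must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(cfg$selection)) {
    w <- c(cfg$selection$w_anc, cfg$selection$w_het, cfg$selection$w_der)
    if (any(w <= 0)) stop("fitness values must be > 0", call. = FALSE)
    ids <- vapply(cfg$inversions, `[[`, "", "id")
    if (!all(cfg$selection$inversion %in% ids)) {
      stop("selection schedule names an unknown inversion", call. = FALSE)
    }
  }
  s <- cfg$sampling
  stopifnot(all(s$population %in% c("migratory", "coastal")), all(s$n >= 1))
  gen <- year_to_generation(s$year, cfg)
  if (any(gen < 0 | gen > cfg$n_generations)) {
    stop("sampling years must map into the simulated generation range",
         call. = FALSE)
  }
  for (pop in c("migratory", "coastal")) {
    n_pop <- if (pop == "migratory") cfg$n_migratory else cfg$n_coastal
    n_per_year <- tapply(s$n[s$population == pop], s$year[s$population == pop], sum)
    if (length(n_per_year) && any(n_per_year > n_pop)) {
      stop("census size of the ", pop,
           " population is smaller than a requested sample", call. = FALSE)
    }
  }
  for (inv in cfg$inversions) {
    if (!inherits(inv, "inversion_spec")) stop("inversions must be inversion_spec objects")
    if (inv$end > cfg$chromosome_length_bp) {
      stop("inversion ", inv$id, " extends beyond the chromosome", call. = FALSE)
    }
  }
  cfg
}

#' Convert calendar years to generations and back
#'
#' Generation `g` corresponds to `year_start + g * generation_time_years`;
#' years are mapped to the nearest generation.
#'
#' @param year Calendar year(s).
#' @param cfg A [sim_config()].
#' @return Integer generation index (or numeric year for the inverse).
#' @export
year_to_generation <- function(year, cfg) {
  as.integer(round((year - cfg$year_start) / cfg$generation_time_years))
}

#' @rdname year_to_generation
#' @param generation Generation index.
#' @export
generation_to_year <- function(generation, cfg) {
  cfg$year_start + generation * cfg$generation_time_years
}
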