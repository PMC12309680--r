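#' Pipeline configuration
#'
#' Bundles per-stage parameters for [run_pipeline()]. Defaults give the
#' demonstration workflow mirroring the study design: simulate two ecotypes
#' over a century, filter and LD-prune to a neutral inversion-excluded set,
#' PCA, karyotype the four inversions, temporal Fs' over all year pairs,
#' permutation FST scans for selected year pairs, diversity scans with
#' inversion contrasts, genotype-frequency trajectory tests, and supervised
#' coastal-ancestry estimation by birth cohort.
#'
#' @param sim A [sim_config()].
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param filters,prune,pca,karyotype,fs,fst,diversity,genotest,ancestry
#'   Named lists of stage parameters; see the function implementations they
#'   are passed to.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            seed = 1L,
                            filters = list(max_site_missing = 0.3,
                                           max_sample_missing = 0.5,
                                           maf = 0.01,
                                           drop_transitions = FALSE),
                            prune = list(window_snps = 50, step_snps = 5,
                                         r2_max = 0.5),
                            pca = list(k = 6),
                            karyotype = list(min_sites = 10),
                            fs = list(population = "NEAC"),
                            fst = list(comparisons = list(c(1907, 2014),
                                                          c(1999, 2011),
                                                          c(2011, 2014)),
                                       window_bp = 30000, step_bp = 15000,
                                       n_perm = 200),
                            diversity = list(groups = list(c("NEAC", 2011),
                                                           c("NCC", 2011)),
                                             d_window_bp = 30000,
                                             pi_window_bp = 50000),
                            genotest = list(alpha = 0.05),
                            ancestry = list(coastal_population = "NCC",
                                            migratory_panel_year = 1975,
                                            class_width_years = 3)) {
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, seed = as.integer(seed), filters = filters,
                 prune = prune, pca = pca, karyotype = karyotype, fs = fs,
                 fst = fst, diversity = diversity, genotest = genotest,
                 ancestry = ancestry),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate, filter/prune, pca, karyotype, fsprime, fst-scan,
#' diversity, genotest and ancestry in order, writing each stage's outputs as
#' plain text under `out_dir` and a JSON run manifest at the end. A stage is
#' skipped when all of its outputs already exist; once a stage actually
#' runs, every downstream stage is rerun too, so deleting one intermediate
#' recomputes only from that point on. All randomness flows from per-stage
#' seeds derived from the master seed, and a rerun into a fresh directory
#' with the same configuration is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage messages.
#' @return The manifest (named list), invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[tempogen] ", sprintf(...))
  path <- function(...) file.path(out_dir, ...)
  seeds <- list(simulate = config$seed, missingness = config$seed + 1L,
                fst = config$seed + 2L, genotest = config$seed + 3L)
  force_rest <- FALSE
  ran <- character()
  stage <- function(name, outputs, run) {
    if (!force_rest && all(file.exists(path(outputs)))) {
      say("stage %-10s cached", name)
      return(invisible(NULL))
    }
    force_rest <<- TRUE
    ran <<- c(ran, name)
    say("stage %-10s running", name)
    run()
  }

  stage("simulate", c("genotypes.vcf", "samples.tsv", "truth_ancestry.tsv",
                      "truth_karyotypes.tsv", "inversions.bed"), function() {
    sim <- simulate_cohorts(config$sim)
    if (!is.null(config$sim$missingness)) {
      sim$geno <- inject_missingness(sim$geno, sim$samples,
                                     config$sim$missingness,
                                     seed = seeds$missingness)
    }
    write_sim_outputs(sim, out_dir)
  })

  stage("filter", c("filtered.vcf", "neutral.vcf", "filter_report.tsv"),
        function() {
    gm <- read_vcf(path("genotypes.vcf"))
    gm <- do.call(filter_sites, c(list(gm), config$filters))
    readr::write_tsv(filter_report(gm), path("filter_report.tsv"),
                     progress = FALSE)
    write_vcf(gm, path("filtered.vcf"))
    inv <- read_bed(path("inversions.bed"))
    neutral <- do.call(ld_prune, c(list(exclude_regions(gm, inv)),
                                   config$prune))
    write_vcf(neutral, path("neutral.vcf"))
  })

  stage("pca", "pca_scores.tsv", function() {
    neutral <- read_vcf(path("neutral.vcf"))
    meta <- read_metadata(path("samples.tsv"))
    p <- run_pca(neutral, k = config$pca$k,
                 groups = meta$population[match(neutral$samples,
                                                meta$sample_id)])
    sc <- tidy(p)
    attr(sc, "explained") <- NULL
    readr::write_tsv(sc, path("pca_scores.tsv"), progress = FALSE)
    readr::write_tsv(tibble::tibble(axis = seq_along(p$explained),
                                    explained = p$explained),
                     path("pca_explained.tsv"), progress = FALSE)
  })

  stage("karyotype", "karyotypes.tsv", function() {
    gm <- read_vcf(path("filtered.vcf"))
    inv <- read_bed(path("inversions.bed"))
    calls <- call_karyotypes(gm, inv, min_sites = config$karyotype$min_sites)
    readr::write_tsv(calls, path("karyotypes.tsv"), progress = FALSE)
  })

  stage("fsprime", "fs_prime.tsv", function() {
    neutral <- read_vcf(path("neutral.vcf"))
    meta <- read_metadata(path("samples.tsv"))
    res <- fs_prime_pairs(neutral, meta, config$fs$population,
                          generation_time_years =
                            config$sim$generation_time_years)
    readr::write_tsv(res, path("fs_prime.tsv"), progress = FALSE)
  })

  stage("fst-scan", c("fst_windows.tsv", "shared_outliers.tsv"), function() {
    gm <- read_vcf(path("filtered.vcf"))
    meta <- read_metadata(path("samples.tsv"))
    pop <- config$fs$population
    all_win <- list(); outlier_sets <- list()
    for (cmp in config$fst$comparisons) {
      ga <- meta$sample_id[meta$population == pop & meta$catch_year == cmp[1]]
      gb <- meta$sample_id[meta$population == pop & meta$catch_year == cmp[2]]
      ga <- intersect(ga, gm$samples); gb <- intersect(gb, gm$samples)
      comp_name <- paste0(cmp[1], "_vs_", cmp[2])
      st <- site_fst(gm, ga, gb)
      win <- window_fst(st, config$fst$window_bp, config$fst$step_bp)
      win <- permutation_q(win, gm, ga, gb, n_perm = config$fst$n_perm,
                           seed = seeds$fst, window_bp = config$fst$window_bp,
                           step_bp = config$fst$step_bp)
      win$comparison <- comp_name
      all_win[[comp_name]] <- win
      af <- afd(gm, ga, gb)
      outlier_sets[[comp_name]] <- af[af$outlier, c("chrom", "pos")]
    }
    readr::write_tsv(dplyr::bind_rows(all_win), path("fst_windows.tsv"),
                     progress = FALSE)
    shared <- if (length(outlier_sets) >= 2) {
      shared_outliers(outlier_sets, min_comparisons = 2)
    } else {
      tibble::tibble(chrom = character(), pos = integer(),
                     n_comparisons = integer(), comparisons = character())
    }
    readr::write_tsv(shared, path("shared_outliers.tsv"), progress = FALSE)
  })

  stage("diversity", c("tajima_windows.tsv", "pi_windows.tsv",
                       "inversion_contrast.tsv"), function() {
    gm <- read_vcf(path("filtered.vcf"))
    meta <- read_metadata(path("samples.tsv"))
    inv <- read_bed(path("inversions.bed"))
    d_all <- list(); pi_all <- list(); contrasts <- list()
    for (grp in config$diversity$groups) {
      ids <- meta$sample_id[meta$population == grp[1] &
                              meta$catch_year == as.integer(grp[2])]
      ids <- intersect(ids, gm$samples)
      gname <- paste0(grp[1], "_", grp[2])
      d <- tajimas_d_windows(gm, ids, window_bp = config$diversity$d_window_bp)
      pw <- pi_windows(gm, ids, window_bp = config$diversity$pi_window_bp)
      d$group <- gname; pw$group <- gname
      d_all[[gname]] <- d; pi_all[[gname]] <- pw
      ct <- region_contrast(d, inv, stat = "d")$regions
      ct$group <- gname
      contrasts[[gname]] <- ct
    }
    readr::write_tsv(dplyr::bind_rows(d_all), path("tajima_windows.tsv"),
                     progress = FALSE)
    readr::write_tsv(dplyr::bind_rows(pi_all), path("pi_windows.tsv"),
                     progress = FALSE)
    readr::write_tsv(dplyr::bind_rows(contrasts),
                     path("inversion_contrast.tsv"), progress = FALSE)
  })

  stage("genotest", c("genotype_frequencies.tsv", "genotype_tests.tsv"),
        function() {
    calls <- readr::read_tsv(path("karyotypes.tsv"), show_col_types = FALSE,
                             progress = FALSE)
    meta <- read_metadata(path("samples.tsv"))
    meta_pop <- meta[meta$population == config$fs$population, ]
    freq_all <- list(); tests <- list()
    for (inv_id in unique(calls$inversion)) {
      cl <- calls[calls$inversion == inv_id, ]
      ft <- genotype_freq_table(cl, meta_pop)
      ft$inversion <- inv_id
      freq_all[[inv_id]] <- ft
      fy <- withr::with_seed(seeds$genotest,
                             fisher_years(ft, alpha = config$genotest$alpha))
      hwe <- purrr::map(split(ft, ft$group), function(tb) {
        cn <- stats::setNames(tb$n, tb$class)
        counts <- c(cn["ANCESTRAL"], cn["HET"], cn["DERIVED"])
        counts[is.na(counts)] <- 0L
        res <- hwe_chisq(counts)
        res$group <- tb$group[1]
        res
      })
      hwe <- dplyr::bind_rows(hwe)
      hwe$group <- as.character(hwe$group)
      hwe$inversion <- inv_id
      hwe$overall_fisher_p <- fy$overall_p
      hwe <- dplyr::left_join(hwe, fy$letters, by = "group")
      tests[[inv_id]] <- hwe
    }
    readr::write_tsv(dplyr::bind_rows(freq_all),
                     path("genotype_frequencies.tsv"), progress = FALSE)
    readr::write_tsv(dplyr::bind_rows(tests), path("genotype_tests.tsv"),
                     progress = FALSE)
  })

  stage("ancestry", c("ancestry_q.tsv", "ancestry_cohorts.tsv"), function() {
    neutral <- read_vcf(path("neutral.vcf"))
    meta <- read_metadata(path("samples.tsv"))
    acfg <- config$ancestry
    pop <- config$fs$population
    panels <- list()
    panels[[acfg$coastal_population]] <-
      intersect(meta$sample_id[meta$population == acfg$coastal_population],
                neutral$samples)
    panels[[pop]] <-
      intersect(meta$sample_id[meta$population == pop &
                                 meta$catch_year == acfg$migratory_panel_year],
                neutral$samples)
    freqs <- panel_freqs(neutral, panels)
    focal <- intersect(meta$sample_id[meta$population == pop],
                       neutral$samples)
    q <- fit_q(neutral, freqs, samples = focal)
    readr::write_tsv(q, path("ancestry_q.tsv"), progress = FALSE)
    co <- cohort_summary(q, meta, paste0("q_", acfg$coastal_population),
                         class_width_years = acfg$class_width_years)
    readr::write_tsv(co$cohorts, path("ancestry_cohorts.tsv"),
                     progress = FALSE)
  })

  manifest <- list(
    package = "tempogen",
    config_hash = rlang::hash(config),
    seed = config$seed,
    stage_seeds = seeds,
    stages_run = ran,
    outputs = sort(list.files(out_dir, pattern = "\\.(tsv|vcf|bed)$"))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  say("done; manifest written")
  invisible(manifest)
}
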