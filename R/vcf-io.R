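#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (v4.x, plain text or gzipped) with GT fields into a [geno]
#' object. Both phased (`|`) and unphased (`/`) separators are accepted;
#' `./.` (or `.`) becomes a missing dosage. Multiallelic records are dropped
#' and counted, matching a biallelic-only analysis.
#'
#' @param path Path to a VCF file.
#' @param sample_subset Optional character vector of sample ids to keep.
#' @return A [geno] object with attribute `"n_multiallelic_dropped"`.
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  validate_vcf_lines(path)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alt)
  keep <- n_alt == 1L
  n_multi <- sum(!keep)
  gt <- gt[keep, , drop = FALSE]
  sites <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = BiocGenerics::start(rr)[keep],
    ref = as.character(VariantAnnotation::ref(vcf))[keep],
    alt = vapply(alt[keep], function(a) as.character(a)[1], "")
  )
  dosage <- gt_to_dosage(gt)
  g <- geno(t(dosage), sites, colnames(gt))
  if (!is.null(sample_subset)) g <- g[sample_subset, ]
  attr(g, "n_multiallelic_dropped") <- n_multi
  g
}

# cheap structural validation so malformed records fail with a line number
validate_vcf_lines <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: missing #CHROM header line", call. = FALSE)
  n_fields <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != n_fields) {
      stop(sprintf("malformed VCF record at line %d: %d fields, expected %d",
                   i, nf, n_fields), call. = FALSE)
    }
  }
  invisible(TRUE)
}

gt_to_dosage <- function(gt) {
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
           "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_,
           "0" = 0L, "1" = 1L)
  d <- lut[gt]
  unknown <- is.na(d) & !(gt %in% names(lut))
  if (any(unknown)) {
    # generic fallback: count "1" alleles, missing if any allele is "."
    gen <- strsplit(gt[unknown], "[/|]")
    d[unknown] <- vapply(gen, function(a) {
      if (any(a == ".")) NA_integer_ else sum(a == "1")
    }, 1L)
  }
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits unphased GT-only records (`0/0`, `0/1`, `1/1`, `./.`); round-trips
#' losslessly through [read_vcf()].
#'
#' @param gm A [geno] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  d <- gm$dosage
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  contigs <- unique(gm$sites$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tempogen",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write sample metadata tables
#'
#' Tab-separated metadata with columns `sample_id`, `population`, `ecotype`,
#' `catch_year`, `birth_year`, `age`.
#'
#' @param path File path.
#' @return A tibble (for the reader), or `path` invisibly (for the writer).
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_metadata
#' @param meta Metadata data frame.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Read and write genomic intervals as BED
#'
#' BED is 0-based half-open on disk; tempogen works in 1-based inclusive
#' coordinates internally, so the conversion happens here, at the boundary.
#'
#' @param path File path.
#' @return `read_bed()` returns a tibble with `chrom`, `start`, `end`
#'   (1-based inclusive) and `name`; `write_bed()` returns `path` invisibly.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name")[1:4],
                           fill = TRUE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) bed$name <- paste0("region_", seq_len(nrow(bed)))
  tibble::tibble(chrom = as.character(bed$chrom),
                 start = as.integer(bed$start) + 1L,   # to 1-based inclusive
                 end = as.integer(bed$end),
                 name = as.character(bed$name))
}

#' @rdname read_bed
#' @param regions Data frame with `chrom`, `start`, `end` in 1-based
#'   inclusive coordinates and optionally `name`.
#' @export
write_bed <- function(regions, path) {
  name <- if ("name" %in% names(regions)) regions$name
          else paste0("region_", seq_len(nrow(regions)))
  writeLines(paste(regions$chrom, regions$start - 1L, regions$end, name,
                   sep = "\t"), path)
  invisible(path)
}

#' Regions table of a simulation's inversions
#'
#' @param config A [sim_config()].
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive), `name`.
#' @export
inversion_regions <- function(config) {
  dplyr::bind_rows(lapply(config$inversions, function(inv) {
    tibble::tibble(chrom = inv$chrom, start = inv$start, end = inv$end,
                   name = inv$id)
  }))
}

#' Write all simulator outputs to disk
#'
#' Writes the VCF, the sample metadata TSV, the truth tables (per-sample
#' coastal ancestry and per-sample karyotypes) and the inversion intervals
#' as BED.
#'
#' @param sim A `cohort_sim` from [simulate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    meta = file.path(dir, "samples.tsv"),
    truth_ancestry = file.path(dir, "truth_ancestry.tsv"),
    truth_karyotypes = file.path(dir, "truth_karyotypes.tsv"),
    inversions = file.path(dir, "inversions.bed")
  )
  write_vcf(sim$geno, paths$vcf)
  write_metadata(sim$samples, paths$meta)
  readr::write_tsv(sim$truth$ancestry, paths$truth_ancestry, progress = FALSE)
  readr::write_tsv(sim$truth$karyotypes, paths$truth_karyotypes, progress = FALSE)
  if (length(sim$config$inversions)) {
    write_bed(inversion_regions(sim$config), paths$inversions)
  }
  invisible(paths)
}
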