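#' Read a plasma variant table
#'
#' Tab-separated, UTF-8, one row per variant call, with header columns
#' `sample_id, patient_id, chrom, pos, ref, alt, gene, variant_class,
#' vaf_percent`; `.` marks missing values (e.g. copy-number calls without a
#' quantifiable VAF). Malformed numeric fields are reported with their row
#' number.
#'
#' @param path Path to the TSV file.
#'
#' @return A tibble of variant observations with a numeric `vaf` column in
#'   percent (NA for calls without a VAF).
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = ".", progress = FALSE)
  req <- c("sample_id", "patient_id", "chrom", "pos", "ref", "alt", "gene",
           "variant_class", "vaf_percent")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("variant table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) {
    warning("variant table ", path, " is empty (header only)")
  }
  for (col in c("pos", "vaf_percent")) {
    num <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.na(tab[[col]]) & is.na(num))
    if (length(bad) > 0) {
      stop("non-numeric `", col, "` in ", path, " at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (value: ", tab[[col]][bad[1]], ")", call. = FALSE)
    }
    tab[[col]] <- num
  }
  tab$vaf <- tab$vaf_percent
  tab
}

#' Write a plasma variant table
#' @param variants Tibble with the variant-table schema (see
#'   [read_variant_table()]).
#' @param path Output TSV path.
#' @export
write_variant_table <- function(variants, path) {
  cols <- c("sample_id", "patient_id", "chrom", "pos", "ref", "alt", "gene",
            "variant_class", "vaf_percent")
  readr::write_tsv(variants[, cols], path, na = ".", progress = FALSE)
}

#' Read a clinical annotation table
#'
#' Comma-separated with header `patient_id, sample_id, sample_date_days,
#' therapy_line_id, therapy_agent, recist_status, imaging_date_days`; all
#' dates are integer days since diagnosis.
#'
#' @param path Path to the CSV file.
#' @return A tibble of per-sample clinical annotations.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_csv(path, col_types = readr::cols(
    patient_id = "c", sample_id = "c", sample_date_days = "d",
    therapy_line_id = "i", therapy_agent = "c", recist_status = "c",
    imaging_date_days = "d"), progress = FALSE)
  req <- c("patient_id", "sample_id", "sample_date_days", "therapy_line_id",
           "recist_status")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("clinical table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Read a genome file (chromosome sizes)
#' @param path TSV with columns `chrom`, `length`.
#' @return A tibble.
#' @export
read_genome_file <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(chrom = "c", length = "d"),
                  progress = FALSE)
}

#' Read a per-sample bin profile (BED-like)
#'
#' Tab-separated `chrom, start, end, value` with 0-based half-open
#' intervals. The value kind (`count` or `log2r`) is declared in a leading
#' comment line `#value_kind=...` or via the `value_kind` argument.
#'
#' @param path Path to the TSV file.
#' @param value_kind Override for the declared value kind.
#' @param sample_id Sample identifier to attach; defaults to the file stem.
#'
#' @return A `bin_profile`.
#' @export
read_bin_profile <- function(path, value_kind = NULL, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  declared <- if (grepl("^#value_kind=", first)) sub("^#value_kind=", "", first) else NULL
  value_kind <- value_kind %||% declared %||%
    stop("value kind undeclared for ", path,
         ": add a '#value_kind=count|log2r' header or pass value_kind",
         call. = FALSE)
  tab <- readr::read_tsv(path, comment = "#",
                         col_names = c("chrom", "start", "end", "value"),
                         col_types = "cddd", progress = FALSE)
  new_bin_profile(tab[, c("chrom", "start", "end")], tab$value, value_kind,
                  sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a bin profile as BED-like TSV with a value-kind header
#' @param profile A `bin_profile`.
#' @param path Output path.
#' @export
write_bin_profile <- function(profile, path) {
  stopifnot(inherits(profile, "bin_profile"))
  writeLines(paste0("#value_kind=", profile$value_kind), path)
  out <- profile$bins
  out$value <- profile$values
  readr::write_tsv(out, path, append = TRUE, col_names = FALSE, progress = FALSE)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits `variants.tsv`, `clinical.csv`, `genome.tsv`, one BED-like bin
#' profile per sample under `bins/`, `ground_truth.tsv`, and the resolved
#' configuration as `config.json`. Output is byte-identical across runs at a
#' fixed seed.
#'
#' @param cohort A `ctdna_cohort` from [simulate_cohort()].
#' @param directory Output directory (created if needed).
#'
#' @return The directory, invisibly.
#' @export
write_fixtures <- function(cohort, directory) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  ok <- dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory, call. = FALSE)
  write_variant_table(cohort$variants, file.path(directory, "variants.tsv"))
  readr::write_csv(cohort$clinical, file.path(directory, "clinical.csv"),
                   progress = FALSE)
  readr::write_tsv(cohort$genome, file.path(directory, "genome.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$ground_truth, file.path(directory, "ground_truth.tsv"),
                   na = "NA", progress = FALSE)
  bin_dir <- file.path(directory, "bins")
  dir.create(bin_dir, showWarnings = FALSE)
  for (df in split(cohort$bins, cohort$bins$sample_id)) {
    prof <- new_bin_profile(df[, c("chrom", "start", "end")], df$log2r, "log2r",
                            sample_id = df$sample_id[1])
    write_bin_profile(prof, file.path(bin_dir, paste0(df$sample_id[1], ".tsv")))
  }
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(directory, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' Read a fixture directory back into a cohort-shaped object
#'
#' Inverse of [write_fixtures()] (the simulator config is echoed but not
#' re-validated).
#'
#' @param directory Directory written by [write_fixtures()].
#' @return A list with `variants`, `bins`, `clinical`, `ground_truth`,
#'   `genome`.
#' @export
read_cohort_fixtures <- function(directory) {
  bin_files <- list.files(file.path(directory, "bins"), full.names = TRUE)
  bins <- dplyr::bind_rows(lapply(bin_files, function(f) {
    p <- read_bin_profile(f)
    out <- p$bins
    out$log2r <- p$values
    out$sample_id <- p$sample_id
    out[, c("sample_id", "chrom", "start", "end", "log2r")]
  }))
  list(
    variants = read_variant_table(file.path(directory, "variants.tsv")),
    bins = bins,
    clinical = read_clinical_table(file.path(directory, "clinical.csv")),
    ground_truth = readr::read_tsv(file.path(directory, "ground_truth.tsv"),
                                   col_types = readr::cols(), progress = FALSE),
    genome = read_genome_file(file.path(directory, "genome.tsv")))
}
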