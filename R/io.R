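#' @importFrom rlang .data
NULL

# profiles are a long tibble (sample_id, probe_id, value) with a value_kind
# attribute so normalization cannot be applied twice unnoticed
new_profiles <- function(df, value_kind) {
  stopifnot(value_kind %in% c("log2_ratio", "z_score"))
  df <- tibble::as_tibble(df)
  if (anyNA(df$value) || any(!is.finite(df$value))) {
    rlang::abort("profile values must be finite and non-missing.")
  }
  attr(df, "value_kind") <- value_kind
  class(df) <- unique(c("cnv_profiles", class(df)))
  df
}

#' Kind of values carried by a profile table
#'
#' @param profiles A profile tibble from [read_logratio_table()],
#'   [simulate_sample()] or [zscore_normalize()].
#' @return `"log2_ratio"` or `"z_score"`.
#' @export
value_kind <- function(profiles) {
  attr(profiles, "value_kind") %||% "log2_ratio"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate (and if needed sort) a probe design
#'
#' A probe design is a tibble with columns `probe_id`, `chrom`, `start`,
#' `end` (1-based inclusive) and `region_class` (`"hotspot"` or
#' `"backbone"`). Probes must be unique by id and non-overlapping within a
#' chromosome; unsorted input is sorted with a warning rather than rejected.
#'
#' @param design A data frame with the columns above.
#' @return The validated design, sorted by (chrom, start).
#' @export
as_probe_design <- function(design) {
  design <- tibble::as_tibble(design)
  needed <- c("probe_id", "chrom", "start", "end", "region_class")
  missing <- setdiff(needed, names(design))
  if (length(missing)) {
    rlang::abort(paste0("probe design lacks columns: ",
                        paste(missing, collapse = ", ")))
  }
  design$chrom <- normalize_chrom(design$chrom)
  check_intervals(design$start, design$end, "probe")
  if (anyDuplicated(design$probe_id)) {
    dup <- design$probe_id[duplicated(design$probe_id)][1]
    rlang::abort(sprintf("duplicate probe id '%s'.", dup))
  }
  bad <- !design$region_class %in% c("hotspot", "backbone")
  if (any(bad)) {
    rlang::abort(sprintf("unknown region_class '%s'.",
                         design$region_class[bad][1]))
  }
  ord <- order(design$chrom, design$start)
  if (!identical(ord, seq_len(nrow(design)))) {
    rlang::warn("probe design was not sorted by (chrom, start); sorting.")
    design <- design[ord, ]
  }
  overlaps <- design |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      bad = any(dplyr::lead(.data$start) <= .data$end, na.rm = TRUE),
      .groups = "drop")
  if (any(overlaps$bad)) {
    rlang::abort(sprintf("overlapping probes on %s.",
                         overlaps$chrom[overlaps$bad][1]))
  }
  class(design) <- unique(c("probe_design", class(design)))
  design
}

#' Read a probe design from a BED5-style file
#'
#' Columns: chrom, start, end, probe id, region class (`hotspot` or
#' `backbone`), tab-delimited, 0-based half-open as in BED. Coordinates are
#' converted to the package's internal 1-based inclusive convention on read.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to the file.
#' @return A probe design tibble (see [as_probe_design()]).
#' @export
read_probe_design <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    rlang::warn(sprintf("'%s' contains no probes; empty design.", path))
    return(as_probe_design(tibble::tibble(
      probe_id = character(), chrom = character(),
      start = integer(), end = integer(), region_class = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5)) {
    rlang::abort(sprintf("malformed probe design line %d in '%s' (%d fields, expected 5).",
                         which(nf < 5)[1], path, nf[nf < 5][1]))
  }
  m <- do.call(rbind, fields)
  start0 <- suppressWarnings(as.numeric(m[, 2]))
  end0 <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    rlang::abort(sprintf("malformed coordinates at probe design line %d in '%s'.",
                         bad[1], path))
  }
  as_probe_design(tibble::tibble(
    probe_id = m[, 4], chrom = m[, 1],
    start = as.integer(start0 + 1), end = as.integer(end0),
    region_class = m[, 5]))
}

#' Write a probe design to a BED5-style file
#'
#' Inverse of [read_probe_design()]: 0-based half-open coordinates on disk.
#'
#' @param design A probe design tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_design <- function(design, path) {
  design <- as_probe_design(design)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", design$chrom,
                   design$start - 1L, design$end,
                   design$probe_id, design$region_class)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a log2-ratio matrix keyed to a probe design
#'
#' The file is a tab-delimited matrix whose header row is
#' `probe_id<TAB>sample1<TAB>...`; each subsequent row carries one probe's
#' log2 ratio in every sample. Rows are matched to the design by probe id,
#' so row order need not match the design. Unknown probe ids and missing
#' values are errors: the pipeline presumes complete post-QC hybridization
#' vectors, and silent imputation would bias the per-chromosome moments used
#' downstream.
#'
#' @param path Path to the TSV.
#' @param design The probe design the ratios are keyed to.
#' @return A long profile tibble with columns `sample_id`, `probe_id`,
#'   `value`, ordered by design then sample, `value_kind = "log2_ratio"`.
#' @export
read_logratio_table <- function(path, design) {
  design <- as_probe_design(design)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (!"probe_id" %in% names(tab)) {
    rlang::abort("first column of the ratio table must be 'probe_id'.")
  }
  unknown <- setdiff(tab$probe_id, design$probe_id)
  if (length(unknown)) {
    rlang::abort(sprintf("probe id '%s' is not in the design.", unknown[1]))
  }
  absent <- setdiff(design$probe_id, tab$probe_id)
  if (length(absent)) {
    rlang::abort(sprintf("design probe '%s' has no row in the ratio table.",
                         absent[1]))
  }
  long <- tab |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "value") |>
    dplyr::select("sample_id", "probe_id", "value")
  if (anyNA(long$value)) {
    bad <- long[is.na(long$value), ][1, ]
    rlang::abort(sprintf("missing ratio for probe '%s' in sample '%s'.",
                         bad$probe_id, bad$sample_id))
  }
  # align to design order within each sample
  long <- long |>
    dplyr::mutate(.ord = match(.data$probe_id, design$probe_id)) |>
    dplyr::arrange(.data$sample_id, .data$.ord) |>
    dplyr::select(-".ord")
  new_profiles(long, "log2_ratio")
}

#' Write a log2-ratio matrix
#'
#' Inverse of [read_logratio_table()].
#'
#' @param profiles Long profile tibble (`sample_id`, `probe_id`, `value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logratio_table <- function(profiles, path) {
  wide <- profiles |>
    tidyr::pivot_wider(id_cols = "probe_id", names_from = "sample_id",
                       values_from = "value")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

cnv_call_cols <- c("sample_id", "chrom", "start", "end", "state",
                   "n_probes", "mean_z", "size_bp")

# empty call tibble with the canonical column set
empty_calls <- function() {
  tibble::tibble(sample_id = character(), chrom = character(),
                 start = integer(), end = integer(), state = character(),
                 n_probes = integer(), mean_z = double(), size_bp = integer())
}

#' Validate a CNV call table
#'
#' Calls are non-normal HMM variants: one row per contiguous same-state
#' segment with its coordinates, probe support and mean z-score. The sign of
#' `mean_z` must agree with the state (negative for `decreased`, positive
#' for `increased`).
#'
#' @param calls A data frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `state`, `n_probes`, `mean_z` (`size_bp` is recomputed).
#' @return The validated tibble sorted by (sample, chrom, start).
#' @export
as_cnv_calls <- function(calls) {
  calls <- tibble::as_tibble(calls)
  missing <- setdiff(setdiff(cnv_call_cols, "size_bp"), names(calls))
  if (length(missing)) {
    rlang::abort(paste0("call table lacks columns: ",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(calls) == 0) return(empty_calls())
  calls$chrom <- normalize_chrom(calls$chrom)
  check_intervals(calls$start, calls$end, "call")
  if (any(!calls$state %in% c("decreased", "increased"))) {
    rlang::abort("call states must be 'decreased' or 'increased' (never 'normal').")
  }
  if (any(calls$n_probes < 1)) rlang::abort("calls need n_probes >= 1.")
  sign_ok <- ifelse(calls$state == "decreased", calls$mean_z < 0,
                    calls$mean_z > 0)
  if (!all(sign_ok)) {
    rlang::abort("sign of mean_z must match the call state.")
  }
  calls$size_bp <- interval_length(calls)
  calls |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start) |>
    dplyr::select(dplyr::all_of(cnv_call_cols), dplyr::everything())
}

#' Write CNV calls as a BED-derived table
#'
#' An 8-column tab-delimited file (BED5 plus state, probe count and mean z),
#' 0-based half-open, one header line starting with `#`. `mean_z` is written
#' with 17 significant digits so [read_cnv_bed()] round-trips bit-exactly.
#'
#' @param calls A CNV call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_bed <- function(calls, path) {
  calls <- as_cnv_calls(calls)
  header <- "#chrom\tstart\tend\tname\tscore\tstate\tn_probes\tmean_z"
  lines <- character(0)
  if (nrow(calls)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%.17g",
                     calls$chrom, calls$start - 1L, calls$end,
                     calls$sample_id, calls$state,
                     calls$n_probes, calls$mean_z)
  }
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

#' Read CNV calls written by [write_cnv_bed()]
#'
#' @param path Path to the call file.
#' @return A CNV call tibble.
#' @export
read_cnv_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_calls())
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(m) != 8) {
    rlang::abort(sprintf("expected 8 columns in '%s', found %d.", path, ncol(m)))
  }
  as_cnv_calls(tibble::tibble(
    sample_id = m[, 4], chrom = m[, 1],
    start = as.integer(as.numeric(m[, 2]) + 1), end = as.integer(as.numeric(m[, 3])),
    state = m[, 6], n_probes = as.integer(m[, 7]),
    mean_z = as.numeric(m[, 8])))
}

#' Build an in-memory control CNV catalog
#'
#' A catalog is the set of CNV intervals seen in a control cohort together
#' with the number of carriers of each, used for rarity filtering.
#'
#' @param records Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive) and `carrier_count`.
#' @param cohort_size Number of control individuals assayed (> 0).
#' @return A `control_catalog` tibble with a `cohort_size` attribute.
#' @export
control_catalog <- function(records, cohort_size) {
  cohort_size <- as.integer(cohort_size)
  if (is.na(cohort_size) || cohort_size <= 0) {
    rlang::abort("`cohort_size` must be a positive integer.")
  }
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    records <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer(), carrier_count = integer())
  }
  records$chrom <- normalize_chrom(records$chrom)
  check_intervals(records$start, records$end, "catalog record")
  records$carrier_count <- as.integer(records$carrier_count)
  if (any(records$carrier_count < 0) ||
      any(records$carrier_count > cohort_size)) {
    rlang::abort("carrier counts must be in [0, cohort_size].")
  }
  records <- dplyr::arrange(records, .data$chrom, .data$start)
  attr(records, "cohort_size") <- cohort_size
  class(records) <- unique(c("control_catalog", class(records)))
  records
}

#' Cohort size of a control catalog
#' @param catalog A `control_catalog`.
#' @return Integer cohort size.
#' @export
cohort_size <- function(catalog) attr(catalog, "cohort_size")

#' Read a control CNV catalog
#'
#' Format: a first line `#cohort_size=<N>`, then tab-delimited BED-style
#' records (chrom, start, end, carrier_count; 0-based half-open).
#'
#' @param path Path to the catalog file.
#' @return A `control_catalog` tibble.
#' @export
read_control_catalog <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0 || !grepl("^#cohort_size=\\d+$", lines[1])) {
    rlang::abort(sprintf("'%s' must begin with '#cohort_size=<N>'.", path))
  }
  n <- as.integer(sub("^#cohort_size=", "", lines[1]))
  body <- lines[-1]
  body <- body[!grepl("^#", body) & nzchar(body)]
  if (length(body) == 0) {
    return(control_catalog(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      carrier_count = integer()), n))
  }
  m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  control_catalog(tibble::tibble(
    chrom = m[, 1],
    start = as.integer(as.numeric(m[, 2]) + 1),
    end = as.integer(as.numeric(m[, 3])),
    carrier_count = as.integer(m[, 4])), n)
}

#' Write a control CNV catalog
#'
#' Inverse of [read_control_catalog()].
#'
#' @param catalog A `control_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_control_catalog <- function(catalog, path) {
  lines <- sprintf("%s\t%d\t%d\t%d", catalog$chrom, catalog$start - 1L,
                   catalog$end, catalog$carrier_count)
  readr::write_lines(c(sprintf("#cohort_size=%d", cohort_size(catalog)), lines),
                     path)
  invisible(path)
}
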