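#' Per-chromosome z-score normalization
#'
#' Transforms each sample's log2 ratios into z-scores using
#' chromosome-specific means and standard deviations (sample sd, n - 1
#' denominator), computed separately for every (sample, chromosome) pair.
#' This makes copy-number states comparable across chromosomes and samples
#' and removes any whole-sample baseline offset exactly. After the
#' transform every chromosome of every sample has mean 0 and sd 1 (to
#' within floating-point error).
#'
#' @param profiles Long profile tibble with `value_kind = "log2_ratio"`.
#' @param design The probe design the profiles are aligned to (supplies the
#'   probe-to-chromosome map).
#' @return A profile tibble of the same shape with
#'   `value_kind = "z_score"`.
#' @export
zscore_normalize <- function(profiles, design) {
  if (value_kind(profiles) != "log2_ratio") {
    rlang::abort("profiles are already z-scores.")
  }
  design <- as_probe_design(design)
  chrom_of <- design$chrom[match(profiles$probe_id, design$probe_id)]
  if (anyNA(chrom_of)) {
    bad <- profiles$probe_id[is.na(chrom_of)][1]
    rlang::abort(sprintf("probe '%s' is not in the design.", bad))
  }
  out <- profiles |>
    dplyr::mutate(.chrom = chrom_of) |>
    dplyr::group_by(.data$sample_id, .data$.chrom) |>
    dplyr::mutate(.n = dplyr::n(), .sd = stats::sd(.data$value),
                  value = (.data$value - mean(.data$value)) / .data$.sd) |>
    dplyr::ungroup()
  if (any(out$.n < 2)) {
    rlang::abort(sprintf(
      "chromosome %s has a single probe; cannot standardize.",
      out$.chrom[out$.n < 2][1]))
  }
  if (any(out$.sd == 0)) {
    rlang::abort(sprintf(
      "zero within-chromosome variance on %s (sample %s).",
      out$.chrom[out$.sd == 0][1], out$sample_id[out$.sd == 0][1]))
  }
  new_profiles(dplyr::select(out, -".chrom", -".n", -".sd"), "z_score")
}
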