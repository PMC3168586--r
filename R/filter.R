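#' Threshold filtering of CNV calls
#'
#' Retains calls passing all three conventional post-call thresholds: size
#' at least `min_size_bp` (the default keeps calls strictly greater than
#' 50 kbp), probe support at least `min_probes`, and |mean z| at least
#' `min_abs_mean_z`. Each threshold is monotone: tightening it can only
#' shrink the retained set. Input order is preserved.
#'
#' @param calls A CNV call tibble.
#' @param policy A [filter_policy()].
#' @return The retained calls.
#' @export
apply_threshold_filters <- function(calls, policy = filter_policy()) {
  calls |>
    dplyr::filter(.data$size_bp >= policy$min_size_bp,
                  .data$n_probes >= policy$min_probes,
                  abs(.data$mean_z) >= policy$min_abs_mean_z)
}

#' Partition calls into large and small
#'
#' A call is large when its size strictly exceeds 500 kbp (by default);
#' everything else is small. The partition is exhaustive and disjoint.
#'
#' @param calls A CNV call tibble.
#' @param policy A [filter_policy()] (`large_size_bp` is the boundary:
#'   large means `size_bp >= large_size_bp`, i.e. > 500,000 with the
#'   default 500,001).
#' @return A list with elements `large` and `small`.
#' @export
classify_large <- function(calls, policy = filter_policy()) {
  is_large <- calls$size_bp >= policy$large_size_bp
  list(large = calls[is_large, , drop = FALSE],
       small = calls[!is_large, , drop = FALSE])
}

#' Carrier frequency of calls in a control catalog
#'
#' For each call, sums the carrier counts of every catalog record matching
#' it at `min_reciprocal_overlap` or better and divides by the catalog's
#' cohort size (capped at 1, since distinct records may share carriers).
#'
#' @param calls A CNV call tibble (or any tibble with `chrom`, `start`,
#'   `end`).
#' @param catalog A [control_catalog()].
#' @param min_reciprocal_overlap Match threshold.
#' @return Numeric vector of frequencies in \[0, 1\], one per call.
#' @export
control_frequency <- function(calls, catalog,
                              min_reciprocal_overlap = 0.5) {
  n_cohort <- cohort_size(catalog)
  if (is.null(n_cohort) || n_cohort == 0) {
    rlang::abort("catalog cohort size must be positive.")
  }
  vapply(seq_len(nrow(calls)), function(i) {
    rec <- catalog[catalog$chrom == calls$chrom[i], ]
    if (nrow(rec) == 0) return(0)
    ro <- reciprocal_overlap(calls$start[i], calls$end[i],
                             rec$start, rec$end)
    min(sum(rec$carrier_count[ro >= min_reciprocal_overlap]) / n_cohort, 1)
  }, numeric(1))
}

#' Rarity filtering against control catalogs
#'
#' Annotates each call with its carrier frequency in every control catalog
#' and retains the calls that are rare — frequency strictly below
#' `max_control_frequency` — in *all* of them. With the 1% default this is
#' the standard rare-CNV definition.
#'
#' @param calls A CNV call tibble.
#' @param catalogs A single [control_catalog()] or a (possibly named) list
#'   of them.
#' @param policy A [filter_policy()].
#' @return The retained calls with one `freq_*` column per catalog.
#' @export
rare_filter <- function(calls, catalogs, policy = filter_policy()) {
  if (inherits(catalogs, "control_catalog")) catalogs <- list(catalogs)
  if (length(catalogs) == 0) rlang::abort("at least one catalog is required.")
  nm <- names(catalogs)
  if (is.null(nm)) nm <- rep("", length(catalogs))
  nm <- ifelse(nzchar(nm), nm, paste0("catalog", seq_along(catalogs)))
  freqs <- purrr::map(catalogs, function(cat) {
    control_frequency(calls, cat, policy$min_reciprocal_overlap)
  })
  annotated <- calls
  for (i in seq_along(freqs)) annotated[[paste0("freq_", nm[i])]] <- freqs[[i]]
  keep <- if (nrow(calls) == 0) {
    logical(0)
  } else {
    Reduce(`&`, purrr::map(freqs, ~ .x < policy$max_control_frequency))
  }
  annotated[keep, , drop = FALSE]
}
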