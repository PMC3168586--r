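#' Call CNVs in a single sample
#'
#' The full calling computation for one sample: per-chromosome z-score
#' normalization (skipped if the profile already carries z-scores), Viterbi
#' decoding of the three-state HMM on each chromosome, assembly of
#' same-state probe runs into segments under the 50-kbp rule, and bridging
#' of nearby same-state segments. Only non-normal segments are returned.
#'
#' Sex chromosomes are excluded by default: with a single male reference,
#' chrX/chrY log2 ratios shift with the sample's sex rather than with copy
#' number, so autosomal calling rules do not transfer.
#'
#' @param profiles Long profile tibble for one sample (log2 ratios or
#'   z-scores), aligned to `design`.
#' @param design The probe design.
#' @param params [hmm_params()].
#' @param policy [merge_policy()].
#' @param include_sex_chroms Call on chrX/chrY as well (default `FALSE`).
#' @return A CNV call tibble (see [as_cnv_calls()]), sorted by
#'   (chrom, start).
#' @export
call_sample <- function(profiles, design, params = hmm_params(),
                        policy = merge_policy(),
                        include_sex_chroms = FALSE) {
  design <- as_probe_design(design)
  ids <- unique(profiles$sample_id)
  if (length(ids) != 1) {
    rlang::abort("`call_sample()` expects exactly one sample; see `call_cnvs()`.")
  }
  if (value_kind(profiles) == "log2_ratio") {
    profiles <- zscore_normalize(profiles, design)
  }
  z_of <- profiles$value[match(design$probe_id, profiles$probe_id)]
  if (anyNA(z_of)) rlang::abort("profile does not cover the full design.")
  chroms <- unique(design$chrom)
  if (!include_sex_chroms) chroms <- setdiff(chroms, c("chrX", "chrY"))
  segs <- purrr::map(chroms, function(cc) {
    sel <- design$chrom == cc
    probes <- design[sel, ]
    z <- z_of[sel]
    path <- viterbi_decode(z, params)
    raw <- states_to_segments(path, probes, z, policy)
    bridge_merge(raw, probes, z, policy)
  }) |> purrr::list_rbind()
  if (nrow(segs) == 0) return(empty_calls())
  as_cnv_calls(dplyr::mutate(
    dplyr::select(segs, -"idx_first", -"idx_last"),
    sample_id = ids))
}

#' Call CNVs across a cohort
#'
#' Applies [call_sample()] to every sample in a long profile tibble and
#' binds the results.
#'
#' @inheritParams call_sample
#' @return One CNV call tibble covering all samples.
#' @export
call_cnvs <- function(profiles, design, params = hmm_params(),
                      policy = merge_policy(),
                      include_sex_chroms = FALSE) {
  kind <- value_kind(profiles)
  profiles |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map(function(p) {
      call_sample(new_profiles(p, kind), design, params, policy,
                  include_sex_chroms)
    }) |>
    purrr::list_rbind() |>
    as_cnv_calls()
}
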