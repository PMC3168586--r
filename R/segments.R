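#' Merge per-probe state assignments into raw segments
#'
#' First stage of variant assembly: maximal runs of consecutive probes in
#' the same non-normal state become segments, but a run is split wherever
#' the start-to-start gap between consecutive probes reaches
#' `max_probe_gap_bp` — two same-state probes only stay in one segment while
#' they are less than 50 kbp apart (by default). Normal probes never form
#' segments.
#'
#' @param states Character vector of decoded states, one per probe (from
#'   [viterbi_decode()]), or a `state_path`.
#' @param probes Probe tibble for one chromosome, sorted by start, with
#'   columns `chrom`, `start`, `end`.
#' @param z Numeric z-score vector aligned to `probes` (used for `mean_z`).
#' @param policy A [merge_policy()].
#' @return A tibble of raw segments with columns `chrom`, `start`, `end`,
#'   `state`, `n_probes`, `mean_z`, `idx_first`, `idx_last` (probe indices
#'   into `probes`), sorted by start.
#' @export
states_to_segments <- function(states, probes, z, policy = merge_policy()) {
  if (inherits(states, "state_path")) states <- states$states
  n <- nrow(probes)
  if (length(states) != n || length(z) != n) {
    rlang::abort("states, z and probes must have matching lengths.")
  }
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), state = character(),
                          n_probes = integer(), mean_z = double(),
                          idx_first = integer(), idx_last = integer())
  if (n == 0) return(empty)
  if (length(unique(probes$chrom)) > 1) {
    rlang::abort("`probes` must cover a single chromosome.")
  }
  # break runs on state change or a start-to-start gap >= the 50-kbp rule
  gap_break <- c(FALSE, diff(probes$start) >= policy$max_probe_gap_bp)
  state_break <- c(TRUE, states[-1] != states[-n])
  run_id <- cumsum(state_break | gap_break)
  keep <- states != "normal"
  if (!any(keep)) return(empty)
  idx <- seq_len(n)
  segs <- tibble::tibble(run = run_id[keep], idx = idx[keep],
                         state = states[keep]) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(idx_first = min(.data$idx), idx_last = max(.data$idx),
                     state = .data$state[1], .groups = "drop")
  segment_table(segs, probes, z)
}

# fill coordinates, probe counts and mean z for segments given by index range
segment_table <- function(segs, probes, z) {
  tibble::tibble(
    chrom = probes$chrom[segs$idx_first],
    start = probes$start[segs$idx_first],
    end = probes$end[segs$idx_last],
    state = segs$state,
    n_probes = segs$idx_last - segs$idx_first + 1L,
    mean_z = vapply(seq_len(nrow(segs)), function(i) {
      mean(z[segs$idx_first[i]:segs$idx_last[i]])
    }, numeric(1)),
    idx_first = segs$idx_first,
    idx_last = segs$idx_last
  ) |> dplyr::arrange(.data$start)
}

#' Bridge nearby same-state segments into single variants
#'
#' Second stage of variant assembly: two adjacent segments of the same state
#' separated by an intervening sequence of at most `bridge_max_probes`
#' probes spanning at most `bridge_max_bp` are called as a single variant
#' together with the intervening probes, whose z-scores then enter `mean_z`
#' and whose count enters `n_probes`. Applied iteratively until no further
#' pair qualifies, so the result is a fixed point (re-applying the function
#' is the identity). Only segments adjacent in genomic order are bridged: a
#' segment of the opposite state between two candidates blocks the bridge.
#'
#' @param segments Raw segment tibble from [states_to_segments()].
#' @param probes,z As in [states_to_segments()].
#' @param policy A [merge_policy()].
#' @return A segment tibble of the same shape.
#' @export
bridge_merge <- function(segments, probes, z, policy = merge_policy()) {
  if (nrow(segments) < 2) return(segments)
  segs <- dplyr::arrange(segments, .data$idx_first)
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(segs)) {
      between_probes <- segs$idx_first[i + 1] - segs$idx_last[i] - 1L
      between_bp <- probes$start[segs$idx_first[i + 1]] -
        probes$end[segs$idx_last[i]] - 1L
      if (segs$state[i + 1] == segs$state[i] &&
          between_probes <= policy$bridge_max_probes &&
          between_bp <= policy$bridge_max_bp) {
        segs$idx_last[i] <- segs$idx_last[i + 1]
        segs <- segs[-(i + 1), ]
        merged_any <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged_any) break
  }
  segment_table(
    tibble::tibble(idx_first = segs$idx_first, idx_last = segs$idx_last,
                   state = segs$state),
    probes, z)
}
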