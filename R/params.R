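#' Three-state HMM parameters
#'
#' Gaussian emission parameters (in z-score units) and transition structure
#' for the decreased/normal/increased copy-number HMM. A heterozygous
#' deletion shifts the log2 ratio by about -1, which over typical aCGH probe
#' noise (sd 0.2-0.4) lands near z = -2.5 to -5; duplications are attenuated
#' (log2(3/2) = +0.585), hence the asymmetric default means. The transition
#' matrix is homogeneous: each state keeps `stay_prob` self-transition mass
#' and splits the remainder evenly between the other two states, leaving all
#' genomic-distance handling to the explicit post-hoc merge rules.
#'
#' @param mean_decreased,mean_normal,mean_increased Emission means (z units).
#' @param sd_decreased,sd_normal,sd_increased Emission standard deviations.
#' @param stay_prob Shared self-transition probability, in (0, 1).
#' @param initial_probs Length-3 probability vector over
#'   (decreased, normal, increased); normal-heavy by default.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(mean_decreased = -2.5, mean_normal = 0, mean_increased = 2,
                       sd_decreased = 1, sd_normal = 1, sd_increased = 1,
                       stay_prob = 0.999,
                       initial_probs = c(0.001, 0.998, 0.001)) {
  means <- c(decreased = mean_decreased, normal = mean_normal,
             increased = mean_increased)
  sds <- c(decreased = sd_decreased, normal = sd_normal,
           increased = sd_increased)
  if (any(!is.finite(means))) rlang::abort("state means must be finite.")
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    rlang::abort("state sds must be finite and > 0.")
  }
  if (!(means["decreased"] < means["normal"] &&
        means["normal"] < means["increased"])) {
    rlang::abort("state means must satisfy decreased < normal < increased.")
  }
  if (!is.finite(stay_prob) || stay_prob <= 0 || stay_prob >= 1) {
    rlang::abort("`stay_prob` must be in (0, 1).")
  }
  initial_probs <- as.numeric(initial_probs)
  if (length(initial_probs) != 3 || any(initial_probs < 0) ||
      abs(sum(initial_probs) - 1) > 1e-8) {
    rlang::abort("`initial_probs` must be 3 non-negative values summing to 1.")
  }
  names(initial_probs) <- copy_states()
  off <- (1 - stay_prob) / 2
  trans <- matrix(off, 3, 3, dimnames = list(copy_states(), copy_states()))
  diag(trans) <- stay_prob
  structure(
    list(means = means, sds = sds, stay_prob = stay_prob,
         initial_probs = initial_probs, transition = trans),
    class = "hmm_params"
  )
}

#' The three copy-number states
#'
#' @return `c("decreased", "normal", "increased")`, the fixed state order
#'   used throughout the package.
#' @export
copy_states <- function() c("decreased", "normal", "increased")

#' Segment merging policy
#'
#' Controls the two-stage merging of per-probe HMM state assignments:
#' consecutive same-state probes are merged into a segment while adjacent
#' probe starts are less than `max_probe_gap_bp` apart, and two same-state
#' segments separated by at most `bridge_max_probes` intervening probes
#' spanning at most `bridge_max_bp` are fused into a single variant together
#' with the intervening probes.
#'
#' @param max_probe_gap_bp Split threshold on the start-to-start gap between
#'   consecutive same-state probes (default 50 kbp).
#' @param bridge_max_probes Maximum number of intervening probes bridged.
#' @param bridge_max_bp Maximum intervening span (bases strictly between the
#'   two segments) bridged.
#' @return An object of class `merge_policy`.
#' @export
merge_policy <- function(max_probe_gap_bp = 50000L,
                         bridge_max_probes = 5L,
                         bridge_max_bp = 10000L) {
  vals <- c(max_probe_gap_bp, bridge_max_probes, bridge_max_bp)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("merge policy thresholds must be positive.")
  }
  structure(
    list(max_probe_gap_bp = as.integer(max_probe_gap_bp),
         bridge_max_probes = as.integer(bridge_max_probes),
         bridge_max_bp = as.integer(bridge_max_bp)),
    class = "merge_policy"
  )
}

#' CNV filtering policy
#'
#' Post-call thresholds. Defaults retain calls strictly greater than 50 kbp
#' with at least 5 probes and |mean z| >= 1.5, classify calls strictly
#' greater than 500 kbp as large, and call an event rare when its carrier
#' frequency is below 1% in every control catalog, matched at 50% reciprocal
#' overlap. The size cutoffs follow the published ">50 kbp" / ">500 kbp"
#' conventions; the probe-count and z thresholds are conventional values,
#' exposed here because published pipelines rarely print them.
#'
#' @param min_size_bp Minimum retained call size (default 50001, i.e.
#'   strictly > 50 kbp).
#' @param min_probes Minimum probe support.
#' @param min_abs_mean_z Minimum |mean z-score|.
#' @param large_size_bp Threshold above which a call is "large" (default
#'   500001, i.e. strictly > 500 kbp).
#' @param max_control_frequency Rarity cutoff on control carrier frequency.
#' @param min_reciprocal_overlap Reciprocal-overlap threshold for matching a
#'   call to control catalog records.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_size_bp = 50001L, min_probes = 5L,
                          min_abs_mean_z = 1.5, large_size_bp = 500001L,
                          max_control_frequency = 0.01,
                          min_reciprocal_overlap = 0.5) {
  if (any(c(min_size_bp, min_probes, min_abs_mean_z, large_size_bp) <= 0)) {
    rlang::abort("filter thresholds must be positive.")
  }
  if (max_control_frequency < 0 || max_control_frequency > 1) {
    rlang::abort("`max_control_frequency` must be in [0, 1].")
  }
  if (min_reciprocal_overlap <= 0 || min_reciprocal_overlap > 1) {
    rlang::abort("`min_reciprocal_overlap` must be in (0, 1].")
  }
  structure(
    list(min_size_bp = as.integer(min_size_bp),
         min_probes = as.integer(min_probes),
         min_abs_mean_z = min_abs_mean_z,
         large_size_bp = as.integer(large_size_bp),
         max_control_frequency = max_control_frequency,
         min_reciprocal_overlap = min_reciprocal_overlap),
    class = "filter_policy"
  )
}

#' Probe noise model for the simulator
#'
#' Independent Gaussian noise per probe plus a single whole-genome baseline
#' offset per sample (drawn once per sample), modelling reference/dye
#' effects. Per-chromosome z-scoring removes the baseline exactly.
#'
#' @param probe_noise_sd Per-probe log2-ratio noise sd (> 0).
#' @param sample_baseline_sd Sd of the per-sample baseline offset (>= 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(probe_noise_sd = 0.2, sample_baseline_sd = 0.05) {
  if (!is.finite(probe_noise_sd) || probe_noise_sd <= 0) {
    rlang::abort("`probe_noise_sd` must be finite and > 0.")
  }
  if (!is.finite(sample_baseline_sd) || sample_baseline_sd < 0) {
    rlang::abort("`sample_baseline_sd` must be finite and >= 0.")
  }
  structure(list(probe_noise_sd = probe_noise_sd,
                 sample_baseline_sd = sample_baseline_sd),
            class = "noise_model")
}
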