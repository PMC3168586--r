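#' Build a seeded recovery benchmark cohort
#'
#' Constructs the package's standard detection benchmark: a hotspot-targeted
#' design on a reduced genome and a cohort in which every sample carries
#' `events_per_sample` embedded CNVs (alternating deletions and
#' duplications), each placed over at least `min_probes_per_event`
#' consecutive probes inside a randomly chosen hotspot region. The truth
#' interval of each event is the exact probe-supported span, so recovery is
#' judged purely on the caller, not on breakpoint extension beyond probe
#' coverage.
#'
#' @param design_spec An [array_design_spec()]; the default reduced genome
#'   gives roughly 10,000 probes.
#' @param n_samples Number of samples to simulate.
#' @param events_per_sample Embedded CNVs per sample.
#' @param min_probes_per_event Minimum probes covered by each event (event
#'   lengths are drawn between this and twice this many probes).
#' @param noise A [noise_model()]. The default puts both the deletion
#'   (|shift|/sd = 5.6) and the attenuated duplication (3.25) well above a
#'   signal-to-noise ratio of 3.
#' @param seed Integer seed.
#' @return A list with `design`, `profiles` (long tibble over all samples)
#'   and `truth` (as in [simulate_cohort()]).
#' @export
simulate_recovery_benchmark <- function(design_spec = array_design_spec(),
                                        n_samples = 20,
                                        events_per_sample = 2,
                                        min_probes_per_event = 15,
                                        noise = noise_model(
                                          probe_noise_sd = 0.18,
                                          sample_baseline_sd = 0.05),
                                        seed = 1) {
  design <- generate_design(design_spec, seed = seed)
  hs <- hotspot_regions(design)
  if (nrow(hs) < events_per_sample) {
    rlang::abort("the design needs at least `events_per_sample` hotspots.")
  }
  with_local_seed(seed + 1L, {
    sample_seeds <- sample.int(2^30, n_samples)
    out <- purrr::map(seq_len(n_samples), function(i) {
      id <- sprintf("bench_%03d", i)
      picks <- sample.int(nrow(hs), events_per_sample)
      kinds <- rep(c("deletion", "duplication"),
                   length.out = events_per_sample)
      specs <- purrr::map(seq_along(picks), function(j) {
        h <- hs[picks[j], ]
        idx <- which(design$chrom == h$chrom & design$start >= h$start &
                       design$end <= h$end)
        k <- sample(min_probes_per_event:(2 * min_probes_per_event), 1)
        first <- sample.int(length(idx) - k + 1, 1)
        run <- idx[first:(first + k - 1)]
        cnv_spec(h$chrom, design$start[run[1]], design$end[run[k]],
                 kinds[j])
      }) |> purrr::list_rbind()
      prof <- simulate_sample(design, specs, noise, sample_seeds[i], id)
      truth <- tibble::tibble(sample_id = id, group = "case",
                              chrom = specs$chrom, start = specs$start,
                              end = specs$end, kind = specs$kind,
                              log2_shift = specs$log2_shift)
      list(prof = prof, truth = truth)
    })
    list(design = design,
         profiles = new_profiles(
           purrr::list_rbind(purrr::map(out, "prof")), "log2_ratio"),
         truth = purrr::list_rbind(purrr::map(out, "truth")))
  })
}
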