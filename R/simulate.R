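#' Specification of a hotspot-targeted array design
#'
#' Describes the simulated array: a set of rearrangement-hotspot regions
#' tiled densely (median probe spacing `hotspot_spacing_bp`) over a sparse
#' genomic backbone (median spacing `backbone_spacing_bp`). The defaults
#' describe a reduced three-chromosome genome that preserves the real
#' platform's spacings and hotspot size while keeping whole-cohort
#' simulations fast; a full-scale design (107 hotspots, ~135,000 probes) is
#' obtained by supplying genome-scale `chrom_sizes`, `n_hotspots = 107` and
#' `n_probes_target = 135000`.
#'
#' @param n_hotspots Number of hotspot regions to place.
#' @param hotspot_spacing_bp Median probe spacing inside hotspots (2.6 kbp).
#' @param backbone_spacing_bp Median probe spacing in the backbone (36 kbp).
#' @param hotspot_size_bp Length of each hotspot region.
#' @param n_probes_target Optional expected total probe count; after
#'   generation a deviation beyond 5% raises a warning.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param probe_length_bp Oligo probe length.
#' @return An object of class `array_design_spec`.
#' @export
array_design_spec <- function(n_hotspots = 18,
                              hotspot_spacing_bp = 2600,
                              backbone_spacing_bp = 36000,
                              hotspot_size_bp = 1200000,
                              n_probes_target = NULL,
                              chrom_sizes = c(chr1 = 30e6, chr2 = 30e6,
                                              chr3 = 30e6),
                              probe_length_bp = 50) {
  if (length(chrom_sizes) == 0 || is.null(names(chrom_sizes))) {
    rlang::abort("`chrom_sizes` must be a named vector of lengths.")
  }
  if (hotspot_spacing_bp <= 0 || backbone_spacing_bp <= 0) {
    rlang::abort("probe spacings must be positive.")
  }
  if (n_hotspots < 0) rlang::abort("`n_hotspots` must be >= 0.")
  if (n_hotspots > 0 && hotspot_size_bp > max(chrom_sizes)) {
    rlang::abort("hotspot regions exceed every chromosome length.")
  }
  names(chrom_sizes) <- normalize_chrom(names(chrom_sizes))
  structure(
    list(n_hotspots = as.integer(n_hotspots),
         hotspot_spacing_bp = hotspot_spacing_bp,
         backbone_spacing_bp = backbone_spacing_bp,
         hotspot_size_bp = as.integer(hotspot_size_bp),
         n_probes_target = n_probes_target,
         chrom_sizes = chrom_sizes,
         probe_length_bp = as.integer(probe_length_bp)),
    class = "array_design_spec")
}

# probe start positions tiling [from, to] with log-normal jittered gaps whose
# median equals `spacing`; gaps are floored at the probe length so probes on
# one chromosome never overlap
tile_positions <- function(from, to, spacing, probe_len, sdlog = 0.25) {
  if (to - from + 1 < probe_len) return(integer(0))
  out <- numeric(0)
  pos <- from
  while (pos + probe_len - 1 <= to) {
    k <- max(64, ceiling((to - pos) / spacing * 1.5))
    gaps <- pmax(stats::rlnorm(k, log(spacing), sdlog), probe_len)
    starts <- pos + cumsum(c(0, gaps))
    keep <- starts + probe_len - 1 <= to
    out <- c(out, starts[keep])
    if (!all(keep)) break
    pos <- starts[length(starts)] +
      max(stats::rlnorm(1, log(spacing), sdlog), probe_len)
  }
  unique(as.integer(round(out)))
}

#' Generate a hotspot-targeted probe design
#'
#' Places `n_hotspots` non-overlapping hotspot regions uniformly at random
#' across the genome, then lays probes with exponential-jitter spacing:
#' median `hotspot_spacing_bp` inside hotspots and `backbone_spacing_bp`
#' elsewhere. Deterministic for a fixed seed.
#'
#' @param spec An [array_design_spec()].
#' @param seed Integer seed.
#' @return A probe design tibble with a `hotspot_regions` attribute
#'   (tibble of `chrom`, `start`, `end`).
#' @export
generate_design <- function(spec = array_design_spec(), seed = 1) {
  stopifnot(inherits(spec, "array_design_spec"))
  with_local_seed(seed, {
    sizes <- spec$chrom_sizes
    # hotspot placement: uniform over chromosomes by length, rejection
    # sampling to keep regions disjoint
    hs <- tibble::tibble(chrom = character(), start = integer(),
                         end = integer())
    if (spec$n_hotspots > 0) {
      eligible <- sizes[sizes >= spec$hotspot_size_bp]
      if (length(eligible) == 0) {
        rlang::abort("hotspot regions exceed every chromosome length.")
      }
      tries <- 0
      while (nrow(hs) < spec$n_hotspots) {
        tries <- tries + 1
        if (tries > 200 * spec$n_hotspots) {
          rlang::abort("could not place non-overlapping hotspots; genome too small.")
        }
        cc <- sample(names(eligible), 1, prob = eligible)
        s <- sample.int(eligible[[cc]] - spec$hotspot_size_bp + 1L, 1)
        e <- s + spec$hotspot_size_bp - 1L
        clash <- any(hs$chrom == cc & hs$start <= e & hs$end >= s)
        if (!clash) {
          hs <- dplyr::bind_rows(hs, tibble::tibble(chrom = cc, start = s,
                                                    end = e))
        }
      }
      hs <- dplyr::arrange(hs, .data$chrom, .data$start)
    }
    probes <- purrr::map(names(sizes), function(cc) {
      len <- sizes[[cc]]
      hsc <- hs[hs$chrom == cc, ]
      # backbone intervals are the complement of the hotspots
      bounds <- c(1L, rbind(hsc$start - 1L, hsc$end + 1L), len)
      starts <- integer(0)
      classes <- character(0)
      for (i in seq(1, length(bounds) - 1, by = 2)) {
        p <- tile_positions(bounds[i], bounds[i + 1],
                            spec$backbone_spacing_bp, spec$probe_length_bp)
        starts <- c(starts, p)
        classes <- c(classes, rep("backbone", length(p)))
      }
      for (i in seq_len(nrow(hsc))) {
        p <- tile_positions(hsc$start[i], hsc$end[i],
                            spec$hotspot_spacing_bp, spec$probe_length_bp)
        starts <- c(starts, p)
        classes <- c(classes, rep("hotspot", length(p)))
      }
      ord <- order(starts)
      tibble::tibble(chrom = cc, start = starts[ord],
                     end = starts[ord] + spec$probe_length_bp - 1L,
                     region_class = classes[ord])
    }) |> purrr::list_rbind()
    probes$probe_id <- sprintf("p%06d", seq_len(nrow(probes)))
    if (!is.null(spec$n_probes_target)) {
      dev <- abs(nrow(probes) - spec$n_probes_target) / spec$n_probes_target
      if (dev > 0.05) {
        rlang::warn(sprintf(
          "generated %d probes, more than 5%% off the target %d.",
          nrow(probes), spec$n_probes_target))
      }
    }
    design <- as_probe_design(probes)
    attr(design, "hotspot_regions") <- hs
    design
  })
}

#' Hotspot regions of a generated design
#' @param design A design from [generate_design()].
#' @return Tibble of hotspot intervals (`chrom`, `start`, `end`).
#' @export
hotspot_regions <- function(design) {
  attr(design, "hotspot_regions") %||%
    tibble::tibble(chrom = character(), start = integer(), end = integer())
}

#' Describe CNVs to embed in simulated samples
#'
#' Builds a tibble of CNV specifications. The default log2-ratio shifts are
#' the two-copy-reference expectations: log2(1/2) = -1 for a heterozygous
#' deletion and log2(3/2) = +0.585 for a single-copy duplication.
#'
#' @param chrom,start,end Interval of each event (1-based inclusive).
#' @param kind `"deletion"` or `"duplication"` (recycled).
#' @param log2_shift Log2-ratio shift applied to probes inside the event;
#'   defaults by kind. Deletions must shift negative, duplications positive.
#' @param carrier_frequency Probability that a simulated individual carries
#'   the event, in \[0, 1\].
#' @return A `cnv_spec` tibble.
#' @export
cnv_spec <- function(chrom, start, end, kind = "deletion",
                     log2_shift = NULL, carrier_frequency = 0) {
  n <- max(length(chrom), length(start))
  df <- tibble::tibble(
    chrom = normalize_chrom(rep_len(chrom, n)),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    kind = rep_len(kind, n),
    carrier_frequency = rep_len(carrier_frequency, n))
  check_intervals(df$start, df$end, "CNV spec")
  if (any(!df$kind %in% c("deletion", "duplication"))) {
    rlang::abort("`kind` must be 'deletion' or 'duplication'.")
  }
  if (is.null(log2_shift)) {
    log2_shift <- ifelse(df$kind == "deletion", -1, log2(3 / 2))
  }
  df$log2_shift <- rep_len(log2_shift, n)
  ok <- ifelse(df$kind == "deletion", df$log2_shift < 0, df$log2_shift > 0)
  if (!all(ok)) {
    rlang::abort("deletion shifts must be < 0 and duplication shifts > 0.")
  }
  if (any(df$carrier_frequency < 0 | df$carrier_frequency > 1)) {
    rlang::abort("`carrier_frequency` must be in [0, 1].")
  }
  df
}

#' Simulate one sample's log2-ratio profile
#'
#' Each probe's value is a per-sample baseline offset, plus the log2 shift
#' of any embedded CNV whose interval covers the probe, plus independent
#' Gaussian probe noise. Deterministic for a fixed seed.
#'
#' @param design A probe design.
#' @param truth_cnvs A `cnv_spec` tibble of events carried by this sample
#'   (the `carrier_frequency` column is ignored here); may have zero rows.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param sample_id Sample name.
#' @return A one-sample profile tibble, `value_kind = "log2_ratio"`.
#' @export
simulate_sample <- function(design, truth_cnvs = NULL,
                            noise = noise_model(), seed = 1,
                            sample_id = "S1") {
  design <- as_probe_design(design)
  if (is.null(truth_cnvs)) truth_cnvs <- cnv_spec(character(), integer(), integer())
  if (nrow(truth_cnvs) > 0) {
    bounds <- design |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(max_end = max(.data$end), .groups = "drop")
    m <- match(truth_cnvs$chrom, bounds$chrom)
    if (anyNA(m)) {
      rlang::abort(sprintf("truth CNV chromosome '%s' is not in the design.",
                           truth_cnvs$chrom[is.na(m)][1]))
    }
    # overlapping opposite-sign events in one genome are not a defined state
    if (nrow(truth_cnvs) > 1) {
      tv <- dplyr::arrange(truth_cnvs, .data$chrom, .data$start)
      same <- tv$chrom == dplyr::lag(tv$chrom)
      ovl <- same & tv$start <= dplyr::lag(tv$end)
      opp <- sign(tv$log2_shift) != sign(dplyr::lag(tv$log2_shift))
      if (any(ovl & opp, na.rm = TRUE)) {
        rlang::abort("overlapping truth CNVs of opposite sign in one sample.")
      }
    }
  }
  with_local_seed(seed, {
    baseline <- stats::rnorm(1, 0, noise$sample_baseline_sd)
    shift <- numeric(nrow(design))
    for (i in seq_len(nrow(truth_cnvs))) {
      hit <- design$chrom == truth_cnvs$chrom[i] &
        design$start >= truth_cnvs$start[i] &
        design$end <= truth_cnvs$end[i]
      shift[hit] <- shift[hit] + truth_cnvs$log2_shift[i]
    }
    value <- baseline + shift +
      stats::rnorm(nrow(design), 0, noise$probe_noise_sd)
    new_profiles(tibble::tibble(sample_id = sample_id,
                                probe_id = design$probe_id,
                                value = value),
                 "log2_ratio")
  })
}

#' Simulate a case-control cohort with known embedded CNVs
#'
#' Every sample independently carries each candidate event with that
#' event's `carrier_frequency` (a Bernoulli draw per sample per event);
#' case and control samples draw from their own candidate lists. Returns
#' the profiles together with the exact per-sample truth.
#'
#' @param design A probe design.
#' @param case_specs,control_specs `cnv_spec` tibbles of candidate events
#'   with carrier frequencies.
#' @param n_cases,n_controls Cohort sizes (> 0).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return A list with `profiles` (long tibble over all samples; case ids
#'   `case_001`..., control ids `ctrl_001`...) and `truth` (tibble
#'   `sample_id`, `group`, `chrom`, `start`, `end`, `kind`, `log2_shift`).
#' @export
simulate_cohort <- function(design, case_specs, control_specs,
                            n_cases, n_controls, noise = noise_model(),
                            seed = 1) {
  if (n_cases <= 0 || n_controls <= 0) {
    rlang::abort("cohort sizes must be positive.")
  }
  with_local_seed(seed, {
    one_group <- function(specs, n, prefix, group) {
      ids <- sprintf("%s_%03d", prefix, seq_len(n))
      seeds <- sample.int(.Machine$integer.max, n)
      res <- purrr::map(seq_len(n), function(i) {
        carried <- if (nrow(specs)) {
          specs[stats::runif(nrow(specs)) < specs$carrier_frequency, ]
        } else {
          specs
        }
        prof <- simulate_sample(design, carried, noise, seeds[i], ids[i])
        truth <- if (nrow(carried)) {
          tibble::tibble(sample_id = ids[i], group = group,
                         chrom = carried$chrom, start = carried$start,
                         end = carried$end, kind = carried$kind,
                         log2_shift = carried$log2_shift)
        } else {
          NULL
        }
        list(prof = prof, truth = truth)
      })
      list(profiles = purrr::list_rbind(purrr::map(res, "prof")),
           truth = purrr::list_rbind(purrr::compact(purrr::map(res, "truth"))))
    }
    cases <- one_group(case_specs, n_cases, "case", "case")
    ctrls <- one_group(control_specs, n_controls, "ctrl", "control")
    truth <- dplyr::bind_rows(cases$truth, ctrls$truth)
    if (nrow(truth) == 0) {
      truth <- tibble::tibble(sample_id = character(), group = character(),
                              chrom = character(), start = integer(),
                              end = integer(), kind = character(),
                              log2_shift = double())
    }
    list(profiles = new_profiles(
           dplyr::bind_rows(cases$profiles, ctrls$profiles), "log2_ratio"),
         truth = truth)
  })
}

#' Score CNV calls against the simulated truth
#'
#' A truth event counts as recovered when some call in the same sample with
#' the matching sign (deletion vs decreased, duplication vs increased)
#' reciprocally overlaps it by at least `min_reciprocal_overlap`. Calls
#' that match no truth event are false calls.
#'
#' @param calls A CNV call tibble.
#' @param truth Truth tibble from [simulate_cohort()] (or with the same
#'   columns).
#' @param min_reciprocal_overlap Match threshold, in (0, 1\].
#' @param n_samples Number of samples over which to average false calls;
#'   defaults to the number of distinct sample ids seen in `truth` and
#'   `calls` together (pass the true cohort size when samples may have
#'   neither truth nor calls).
#' @return A list of class `recovery_report`: `sensitivity`,
#'   `false_calls_per_sample`, `n_truth`, `n_matched`, `n_false`, and a
#'   `matches` tibble pairing each recovered truth event with its call.
#' @export
score_recovery <- function(calls, truth, min_reciprocal_overlap = 0.5,
                           n_samples = NULL) {
  if (min_reciprocal_overlap <= 0 || min_reciprocal_overlap > 1) {
    rlang::abort("`min_reciprocal_overlap` must be in (0, 1].")
  }
  if (is.null(n_samples)) {
    n_samples <- dplyr::n_distinct(c(truth$sample_id, calls$sample_id))
  }
  state_of <- c(deletion = "decreased", duplication = "increased")
  matched <- logical(nrow(truth))
  call_used <- logical(nrow(calls))
  matches <- list()
  for (i in seq_len(nrow(truth))) {
    cand <- which(calls$sample_id == truth$sample_id[i] &
                    calls$chrom == truth$chrom[i] &
                    calls$state == state_of[[truth$kind[i]]])
    if (!length(cand)) next
    ro <- reciprocal_overlap(truth$start[i], truth$end[i],
                             calls$start[cand], calls$end[cand])
    hit <- cand[ro >= min_reciprocal_overlap]
    if (length(hit)) {
      best <- hit[which.max(ro[ro >= min_reciprocal_overlap])]
      matched[i] <- TRUE
      call_used[hit] <- TRUE
      matches[[length(matches) + 1]] <- tibble::tibble(
        sample_id = truth$sample_id[i], chrom = truth$chrom[i],
        truth_start = truth$start[i], truth_end = truth$end[i],
        call_start = calls$start[best], call_end = calls$end[best],
        overlap = max(ro))
    }
  }
  n_truth <- nrow(truth)
  structure(
    list(sensitivity = if (n_truth > 0) sum(matched) / n_truth else NA_real_,
         false_calls_per_sample = if (n_samples > 0) {
           sum(!call_used) / n_samples
         } else {
           NA_real_
         },
         n_truth = n_truth, n_matched = sum(matched),
         n_false = sum(!call_used),
         matches = purrr::list_rbind(matches)),
    class = "recovery_report")
}
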