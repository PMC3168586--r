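#' Configure an end-to-end run
#'
#' Bundles everything [run_end_to_end()] needs. Two modes:
#' * `"simulate"` — generate a probe design and a case/control cohort with
#'   embedded CNVs, then call, filter and test; the truth and a recovery
#'   report are part of the output.
#' * `"files"` — read a probe design and case/control log2-ratio matrices
#'   from disk.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param out_dir Directory for the output artifacts (created if absent).
#' @param seed Integer seed controlling every random draw of the run.
#' @param design_spec [array_design_spec()] (simulate mode).
#' @param case_specs,control_specs `cnv_spec` tibbles (simulate mode).
#' @param n_cases,n_controls Cohort sizes (simulate mode).
#' @param noise [noise_model()] (simulate mode).
#' @param design_path,case_ratios_path,control_ratios_path Input files
#'   (files mode).
#' @param catalogs List of [control_catalog()] objects or paths readable by
#'   [read_control_catalog()]; optional (rarity filtering is skipped when
#'   empty).
#' @param params,policy,filters [hmm_params()], [merge_policy()],
#'   [filter_policy()].
#' @param include_sex_chroms Passed to [call_cnvs()].
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "files"), out_dir, seed = 1,
                       design_spec = array_design_spec(),
                       case_specs = NULL, control_specs = NULL,
                       n_cases = 20, n_controls = 20,
                       noise = noise_model(),
                       design_path = NULL, case_ratios_path = NULL,
                       control_ratios_path = NULL,
                       catalogs = list(),
                       params = hmm_params(), policy = merge_policy(),
                       filters = filter_policy(),
                       include_sex_chroms = FALSE) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
              design_spec = design_spec, case_specs = case_specs,
              control_specs = control_specs, n_cases = n_cases,
              n_controls = n_controls, noise = noise,
              design_path = design_path,
              case_ratios_path = case_ratios_path,
              control_ratios_path = control_ratios_path,
              catalogs = catalogs, params = params, policy = policy,
              filters = filters,
              include_sex_chroms = include_sex_chroms)
  if (mode == "files") {
    for (p in c(cfg$design_path, cfg$case_ratios_path,
                cfg$control_ratios_path)) {
      if (!is.null(p) && !file.exists(p)) {
        rlang::abort(sprintf("input path does not exist: '%s'", p),
                     class = "cnvburden_usage_error")
      }
    }
    if (is.null(cfg$design_path) || is.null(cfg$case_ratios_path)) {
      rlang::abort("files mode needs `design_path` and `case_ratios_path`.",
                   class = "cnvburden_usage_error")
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full simulate/load - call - filter - burden workflow
#'
#' Executes every pipeline stage in order and writes the artifacts to
#' `config$out_dir`: `calls.tsv` (all raw calls), `filtered_calls.tsv`,
#' `rare_calls.tsv` (when catalogs are configured), `burden.tsv`, and in
#' simulate mode `truth.tsv` and `recovery.tsv`. Every file starts with a
#' provenance header recording the package version and the seed, and the
#' whole run is a pure function of the configuration: the same config
#' yields byte-identical outputs. If any stage fails, files written so far
#' are removed and the error names the stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results: `calls`,
#'   `filtered_calls`, `rare_calls`, `burden` (a `cnv_fisher`), `recovery`
#'   (simulate mode), and `paths` of the written files.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(stage, e) {
    unlink(written)
    rlang::abort(sprintf("stage '%s' failed: %s", stage,
                         conditionMessage(e)),
                 class = "cnvburden_stage_error")
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) on_fail(name, e))
  }
  prov <- sprintf("#cnvburden %s; seed=%d; stay_prob=%g; gap=%d; bridge=%d/%d",
                  as.character(utils::packageVersion("cnvburden")),
                  config$seed, config$params$stay_prob,
                  config$policy$max_probe_gap_bp,
                  config$policy$bridge_max_probes,
                  config$policy$bridge_max_bp)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    tmp <- paste0(path, ".body")
    writer(tmp)
    readr::write_lines(c(prov, readr::read_lines(tmp)), path)
    unlink(tmp)
    written <<- c(written, path)
    path
  }

  truth <- NULL; case_ids <- NULL; ctrl_ids <- NULL
  if (config$mode == "simulate") {
    sim <- stage("simulate", {
      design <- generate_design(config$design_spec, seed = config$seed)
      cs <- config$case_specs %||% cnv_spec(character(), integer(), integer())
      ks <- config$control_specs %||% cnv_spec(character(), integer(), integer())
      cohort <- simulate_cohort(design, cs, ks, config$n_cases,
                                config$n_controls, config$noise,
                                seed = config$seed + 1L)
      list(design = design, cohort = cohort)
    })
    design <- sim$design
    profiles <- sim$cohort$profiles
    truth <- sim$cohort$truth
    case_ids <- sprintf("case_%03d", seq_len(config$n_cases))
    ctrl_ids <- sprintf("ctrl_%03d", seq_len(config$n_controls))
  } else {
    loaded <- stage("load", {
      design <- read_probe_design(config$design_path)
      cases <- read_logratio_table(config$case_ratios_path, design)
      ctrls <- if (!is.null(config$control_ratios_path)) {
        read_logratio_table(config$control_ratios_path, design)
      } else {
        NULL
      }
      list(design = design, cases = cases, ctrls = ctrls)
    })
    design <- loaded$design
    case_ids <- unique(loaded$cases$sample_id)
    ctrl_ids <- if (!is.null(loaded$ctrls)) unique(loaded$ctrls$sample_id)
    profiles <- new_profiles(dplyr::bind_rows(loaded$cases, loaded$ctrls),
                             "log2_ratio")
  }

  calls <- stage("call", {
    call_cnvs(profiles, design, config$params, config$policy,
              config$include_sex_chroms)
  })
  written <- c(written, emit("calls.tsv", function(p) write_cnv_bed(calls, p)))

  filtered <- stage("filter", apply_threshold_filters(calls, config$filters))
  written <- c(written,
               emit("filtered_calls.tsv",
                    function(p) write_cnv_bed(filtered, p)))

  rare <- filtered
  if (length(config$catalogs)) {
    rare <- stage("rarity", {
      cats <- purrr::map(config$catalogs, function(x) {
        if (inherits(x, "control_catalog")) x else read_control_catalog(x)
      })
      rare_filter(filtered, cats, config$filters)
    })
    written <- c(written,
                 emit("rare_calls.tsv", function(p) {
                   write_cnv_bed(dplyr::select(
                     rare, dplyr::all_of(cnv_call_cols)), p)
                 }))
  }

  burden <- NULL
  if (!is.null(ctrl_ids) && length(ctrl_ids)) {
    burden <- stage("burden", {
      burden_test(filtered[filtered$sample_id %in% case_ids, ], case_ids,
                  filtered[filtered$sample_id %in% ctrl_ids, ], ctrl_ids,
                  config$filters$large_size_bp - 1L)
    })
    written <- c(written, emit("burden.tsv", function(p) {
      readr::write_tsv(glance(burden), p, progress = FALSE)
    }))
  }

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- stage("evaluate", {
      score_recovery(calls, truth,
                     n_samples = length(case_ids) + length(ctrl_ids))
    })
    written <- c(written, emit("truth.tsv", function(p) {
      readr::write_tsv(truth, p, progress = FALSE)
    }))
    written <- c(written, emit("recovery.tsv", function(p) {
      readr::write_tsv(tidy(recovery), p, progress = FALSE)
    }))
  }

  invisible(list(calls = calls, filtered_calls = filtered,
                 rare_calls = rare, burden = burden, recovery = recovery,
                 paths = unique(written)))
}
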