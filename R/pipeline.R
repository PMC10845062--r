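# Declarative pipeline orchestration: simulate/load -> edge-wise CWAS ->
# row-wise BH -> network/hub summaries -> integration model -> ROC sweep,
# or the two-group contrast in group mode. Every run writes a JSON manifest
# echoing the full effective configuration (no silent defaults), the seed,
# package/R versions and per-stage wall time.

#' Default run configuration
#'
#' @param seed RNG seed for the run
#' @param out_dir output directory
#' @return nested list understood by [run_pipeline()]; every field shown is
#'   an effective setting echoed into the run manifest.
#' @export
default_run_config <- function(seed = 1L, out_dir = "deltacwas_run") {
  list(
    mode = "longitudinal",            # or "group"
    seed = as.integer(seed),
    q = 0.05,
    out_dir = out_dir,
    cohort_dir = NULL,                # read an existing cohort ...
    simulate = list(                  # ... or simulate one (takes precedence
      n_subjects = 200L,              #     only when cohort_dir is NULL)
      planted_edges = NULL,
      sex_effect = -0.24,
      baseline_within = 0.3, baseline_between = 0.05,
      baseline_sd = 0.1, delta_sd = 0.1, symptom_noise_sd = 0),
    target_rois = "stn_R",            # integration seed set
    percentiles = seq(50, 95, by = 5),
    standardize = TRUE)
}

load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_run_config()
  utils::modifyList(base, cfg)
}

get_pipeline_cohort <- function(config) {
  if (!is.null(config$cohort_dir)) {
    list(dataset = read_cohort(config$cohort_dir), truth = NULL)
  } else {
    sim <- config$simulate %||% default_run_config()$simulate
    pe <- sim$planted_edges
    if (!is.null(pe)) pe <- as.data.frame(pe)
    cfg <- sim_config(
      n_subjects = sim$n_subjects %||% 200L,
      planted_edges = pe,
      sex_effect = sim$sex_effect %||% -0.24,
      baseline_within = sim$baseline_within %||% 0.3,
      baseline_between = sim$baseline_between %||% 0.05,
      baseline_sd = sim$baseline_sd %||% 0.1,
      delta_sd = sim$delta_sd %||% 0.1,
      symptom_noise_sd = sim$symptom_noise_sd %||% 0,
      seed = config$seed)
    if (identical(config$mode, "group")) {
      simulate_two_group(cfg, group_shift = sim$group_shift,
                         n_patients = sim$n_patients %||% 29L,
                         n_controls = sim$n_controls %||% 29L)
    } else {
      simulate_cohort(cfg)
    }
  }
}

#' Run the full analysis pipeline from a configuration
#'
#' Longitudinal mode: edge-wise baseline-adjusted OLS, row-wise BH,
#' frequency table, hub scores, cortical-integration regression for the
#' configured seed set, and the percentile-sweep ROC of the (sign-aligned)
#' integration change. Group mode: edge-wise and integration-level group
#' contrasts. All result tables, a cohort copy (when simulated) and a JSON
#' manifest land in `config$out_dir`.
#'
#' @param config list as returned by [default_run_config()] (or read from a
#'   JSON config file)
#' @param stages subset of stages to run (`"cwas"`, `"summarize"`,
#'   `"integrate"`, `"roc"`); earlier stages a later one needs are always
#'   run in memory
#' @return invisible list of in-memory results
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("cwas", "summarize", "integrate", "roc")) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  timing <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }
  results <- list()

  sim <- tick("cohort", get_pipeline_cohort(config))
  dataset <- sim$dataset
  if (!is.null(sim$truth)) {
    write_cohort(dataset, file.path(out, "cohort"))
    write_truth(sim$truth, file.path(out, "truth.json"))
  }
  results$dataset <- dataset
  results$truth <- sim$truth

  if (identical(config$mode, "group")) {
    gr <- tick("group_edges", fit_group_edge_anova(dataset, q = config$q))
    write_edge_results(gr, file.path(out, "group_edge_results.tsv"),
                       seed = config$seed)
    gi <- tick("group_integration",
               integration_group_anova(dataset, config$target_rois))
    jsonlite::write_json(gi, file.path(out, "group_integration.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    results$group_edges <- gr
    results$group_integration <- gi
  } else {
    res <- tick("cwas", {
      r <- fit_edge_models(dataset,
                           edge_model_spec(standardize = config$standardize))
      rowwise_bh(r, q = config$q)
    })
    write_edge_results(res, file.path(out, "edge_results.tsv"),
                       seed = config$seed)
    results$edge_results <- res

    if ("summarize" %in% stages) {
      ft <- tick("frequency", network_frequency(res))
      write_frequency_table(ft, file.path(out, "frequency_table.tsv"))
      hs <- tick("hubs", hub_scores(res))
      write_hub_scores(hs, file.path(out, "hub_scores.tsv"))
      results$frequency <- ft
      results$hubs <- hs
    }
    if (any(c("integrate", "roc") %in% stages)) {
      prof <- tick("integration",
                   cortical_integration(dataset, config$target_rois))
      rep <- fit_integration_model(prof, dataset,
                                   standardize = config$standardize)
      write_model_report(rep, file.path(out, "integration_report.json"))
      results$integration_profiles <- prof
      results$integration_report <- rep
      if ("roc" %in% stages) {
        # score: mean cortical change of the seed set, sign-aligned so that
        # larger score corresponds to higher symptom load
        b <- rep$terms$beta[rep$terms$term == "mean_delta"]
        score <- prof$mean_delta * sign(b)
        roc <- tick("roc", roc_percentile_sweep(score, dataset$symptoms_tp2,
                                                config$percentiles))
        write_tsv(roc, file.path(out, "roc_table.tsv"))
        results$roc <- roc
      }
    }
  }

  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   out_dir = out,
                   config_hash = fnv1a(jsonlite::toJSON(
                     config[setdiff(names(config), "out_dir")],
                     auto_unbox = TRUE, digits = NA, force = TRUE)),
                   seed = config$seed,
                   parcellation_hash = parcellation_hash(dataset$scheme),
                   n_subjects = n_subjects(dataset),
                   stages = stages, timing = timing,
                   package_version =
                     as.character(utils::packageVersion("deltacwas")),
                   r_version = R.version.string,
                   written = stamp())
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(results)
}
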