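#' Configuration for a full pipeline run
#'
#' Either `responses_csv` + `scales` (a path to YAML/JSON metadata or a
#' `scale_definition` data.frame) for real data, or `synthetic` (a
#' [synthetic_spec()]) for simulated data.
#'
#' @param responses_csv path to a wide respondents x items CSV.
#' @param scales scale metadata path or `scale_definition`.
#' @param synthetic a `synthetic_spec` (alternative to file input).
#' @param method correlation method (`"spearman"` or `"pearson"`).
#' @param p_threshold,share_threshold,min_correlation redundancy screening
#'   thresholds, see [find_bad_pairs()].
#' @param gamma EBIC hyperparameter (conventional range 0 to 0.5).
#' @param lambda optional fixed penalty overriding EBIC selection.
#' @param n_points,min_ratio penalty path geometry.
#' @param B bootstrap replicates (0 skips all accuracy/stability stages).
#' @param drop_levels case-dropping fractions.
#' @param alpha significance level for difference tests.
#' @param seed master seed for all resampling (and simulation, unless the
#'   synthetic spec carries its own).
#' @param top_k how many top nodes per metric to report.
#' @param output_dir where artifacts are written (`NULL`: nothing written).
#' @return A list of class `run_config`.
#' @export
run_config <- function(responses_csv = NULL, scales = NULL, synthetic = NULL,
                       method = "spearman", p_threshold = 0.05,
                       share_threshold = 0.75, min_correlation = 0.5,
                       gamma = 0.25, lambda = NULL,
                       n_points = 100, min_ratio = 0.01,
                       B = 1000, drop_levels = seq(0.1, 0.9, by = 0.1),
                       alpha = 0.05, seed = 1, top_k = 3,
                       output_dir = NULL) {
  structure(list(responses_csv = responses_csv, scales = scales,
                 synthetic = synthetic, method = method,
                 p_threshold = p_threshold, share_threshold = share_threshold,
                 min_correlation = min_correlation,
                 gamma = gamma, lambda = lambda,
                 n_points = n_points, min_ratio = min_ratio,
                 B = B, drop_levels = drop_levels, alpha = alpha,
                 seed = seed, top_k = top_k, output_dir = output_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Returns findings rather than throwing: rows with `level` (`"error"` or
#' `"warning"`) and `message`. A `gamma` outside the 0-0.5 range is only a
#' warning — values in that range are the convention, higher values are
#' legal but unusually conservative.
#'
#' @param config a `run_config`.
#' @return A data.frame of findings (zero rows when the config is clean).
#' @export
validate_config <- function(config) {
  findings <- list()
  add <- function(level, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = message, stringsAsFactors = FALSE)
  has_files <- !is.null(config$responses_csv)
  has_synth <- !is.null(config$synthetic)
  if (!has_files && !has_synth)
    add("error", "no input: supply responses_csv + scales, or a synthetic spec")
  if (has_files && is.null(config$scales))
    add("error", "responses_csv given without scale metadata")
  if (has_files && has_synth)
    add("warning", "both file input and synthetic spec given; file input wins")
  if (!config$method %in% c("spearman", "pearson"))
    add("error", paste0("unknown correlation method: ", config$method))
  if (config$share_threshold <= 0 || config$share_threshold >= 1)
    add("error", "share_threshold must lie strictly between 0 and 1")
  if (config$p_threshold <= 0 || config$p_threshold >= 1)
    add("error", "p_threshold must lie strictly between 0 and 1")
  if (config$min_correlation < 0 || config$min_correlation >= 1)
    add("error", "min_correlation must lie in [0, 1)")
  if (config$gamma < 0 || config$gamma > 0.5)
    add("warning", sprintf(
      "gamma = %g is outside the conventional 0-0.5 range (higher values give sparser models)",
      config$gamma))
  if (config$B < 0) add("error", "B must be nonnegative")
  if (any(config$drop_levels <= 0 | config$drop_levels >= 1))
    add("error", "drop_levels must lie strictly between 0 and 1")
  if (config$alpha <= 0 || config$alpha > 1)
    add("error", "alpha must lie in (0, 1]")
  if (length(findings) == 0)
    return(data.frame(level = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

# Resolved-config serialization: output_dir is a property of where the run
# lands, not of the analysis, and is omitted so identical analyses written
# to different directories produce identical artifacts.
resolve_config_list <- function(config) {
  out <- unclass(config)
  out$scales <- if (is.data.frame(out$scales)) "inline scale_definition" else out$scales
  out$synthetic <- if (!is.null(out$synthetic)) unclass(out$synthetic) else NULL
  out$output_dir <- NULL
  out
}

#' Run the full symptom-network pipeline
#'
#' Stage order: data ingestion (file or simulation) with reverse coding →
#' redundancy screening and node removal → correlation matrix →
#' graphical-lasso estimation with EBIC selection → expected influence and
#' bridge expected influence → edge-weight bootstrap, case-dropping
#' stability for EI and bridge EI, and bootstrapped difference tests.
#' With `B = 0` the three accuracy stages are skipped (their report fields
#' stay `NULL`) with a warning.
#'
#' All artifacts (resolved config, redundancy report, edge list, adjacency,
#' GraphML, centrality table, bootstrap CIs, stability samples, report
#' JSON) are written under `config$output_dir` when set; outputs contain no
#' timestamps, so a rerun with the same seed writes byte-identical files.
#'
#' @param config a `run_config`.
#' @return A `run_report` list: item counts before/after reduction,
#'   selected penalty and EBIC, edge count, top-k nodes per metric, CS
#'   coefficients, significant difference-test pairs, seed, version.
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  errs <- findings$message[findings$level == "error"]
  if (length(errs) > 0)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  for (w in findings$message[findings$level == "warning"]) warning(w)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(fn, ...) if (!is.null(out_dir)) fn(...)

  # --- ingestion ------------------------------------------------------
  truth <- NULL
  m <- stage("ingestion", {
    if (!is.null(config$responses_csv)) {
      scales <- if (is.data.frame(config$scales)) config$scales
                else read_scale_metadata(config$scales)
      load_responses(config$responses_csv, scales, id_column = "respondent_id")
    } else {
      sim <- simulate_study_data(config$synthetic)
      truth <- sim$truth
      reverse_code(sim$responses)
    }
  })
  emit(yaml::write_yaml, resolve_config_list(config),
       file.path(out_dir, "resolved_config.yaml"))

  # --- redundancy reduction -------------------------------------------
  red <- stage("redundancy", reduce_items(
    m, method = config$method, p_threshold = config$p_threshold,
    share_threshold = config$share_threshold,
    min_correlation = config$min_correlation))
  m_red <- red$responses
  emit(write_redundancy_json, red$report, file.path(out_dir, "redundancy.json"))

  # --- estimation ------------------------------------------------------
  cm <- stage("correlation", correlation_matrix(m_red, method = config$method))
  emit(write_correlation_csv, cm, file.path(out_dir, "correlation.csv"))
  model <- stage("estimation", estimate_network(
    cm, gamma = config$gamma, lambda = config$lambda,
    n_points = config$n_points, min_ratio = config$min_ratio))
  emit(write_network, model,
       edge_list_path = file.path(out_dir, "edge_list.csv"),
       adjacency_path = file.path(out_dir, "adjacency.csv"),
       graphml_path = file.path(out_dir, "network.graphml"))

  # --- interpretation --------------------------------------------------
  centr <- stage("centrality", centrality_table(model))
  emit(write_centrality_csv, centr, file.path(out_dir, "centrality.csv"))
  top <- lapply(setNames(nm = c("ei1", "ei2", "bridge_ei1", "bridge_ei2")),
                function(mt) rank_nodes(centr, mt, config$top_k))

  # --- accuracy & stability -------------------------------------------
  boot <- stability <- diff_sig <- NULL
  cs_ei <- cs_bridge <- NULL
  if (config$B > 0) {
    est <- estimator_config(method = config$method, gamma = config$gamma,
                            lambda = config$lambda,
                            n_points = config$n_points,
                            min_ratio = config$min_ratio)
    boot <- stage("edge_bootstrap", nonparametric_bootstrap(
      m_red, est, B = config$B, seed = config$seed, alpha = config$alpha))
    emit(write_bootstrap_csv, boot,
         ci_path = file.path(out_dir, "edge_bootstrap_ci.csv"))
    stability <- stage("case_dropping", case_dropping_bootstrap(
      m_red, est, statistic = c("EI", "bridge_EI"),
      drop_levels = config$drop_levels, B = config$B,
      seed = config$seed + 1L))
    cs_ei <- stability$EI$cs_coefficient
    cs_bridge <- stability$bridge_EI$cs_coefficient
    emit(write_stability_csv, stability$EI, file.path(out_dir, "stability_ei.csv"))
    emit(write_stability_csv, stability$bridge_EI,
         file.path(out_dir, "stability_bridge_ei.csv"))
    dt <- stage("difference_tests",
                difference_tests_all(boot, what = "EI", alpha = config$alpha))
    diff_sig <- dt[dt$significant, c("a", "b", "estimate", "ci_lower", "ci_upper")]
    rownames(diff_sig) <- NULL
    emit(write.csv, dt, file.path(out_dir, "difference_tests_ei.csv"),
         row.names = FALSE)
  } else {
    warning("B = 0: bootstrap accuracy and stability stages skipped")
  }

  report <- structure(
    list(n_respondents = m$n,
         n_items_entered = m$p,
         n_items_retained = m_red$p,
         removed_items = red$report$removed_items,
         missing_fraction = m$missing_fraction,
         selected_lambda = model$selected_lambda,
         gamma = model$gamma,
         ebic = min(model$ebic_values),
         edge_count = sum(model$W[upper.tri(model$W)] != 0),
         top_nodes = top,
         cs_ei = cs_ei,
         cs_bridge_ei = cs_bridge,
         n_significant_ei_differences = if (is.null(diff_sig)) NULL else nrow(diff_sig),
         significant_ei_differences = diff_sig,
         seed = config$seed,
         version = as.character(utils::packageVersion("symptomnet"))),
    class = "run_report")
  if (!is.null(out_dir))
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(report, "model") <- model
  attr(report, "centrality") <- centr
  attr(report, "truth") <- truth
  attr(report, "bootstrap") <- boot
  attr(report, "stability") <- stability
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Symptom network run (seed %d): %d respondents, %d -> %d items\n",
              x$seed, x$n_respondents, x$n_items_entered, x$n_items_retained))
  cat(sprintf("Selected penalty %.4g (gamma %g), %d edges\n",
              x$selected_lambda, x$gamma, x$edge_count))
  cat("Top nodes by EI1:        ", paste(x$top_nodes$ei1, collapse = ", "), "\n")
  cat("Top nodes by bridge EI1: ", paste(x$top_nodes$bridge_ei1, collapse = ", "), "\n")
  if (!is.null(x$cs_ei))
    cat(sprintf("CS coefficients: EI %.2f, bridge EI %.2f\n",
                x$cs_ei, x$cs_bridge_ei))
  invisible(x)
}
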