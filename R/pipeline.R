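CONFIG_KEYS <- c("inputs", "synthetic", "target", "response", "k_min", "k_max",
                 "k_step", "delta_threshold", "n_perm", "identity_rule", "tau",
                 "tau_quantile", "target_selection", "moran_k", "moran_n_perm",
                 "correlation_method", "seed", "outdir")

#' Target spots by top quantile of the target-cell proportion
#'
#' Convenience selector for deconvolution-driven analyses: the spots whose
#' target cell-type proportion reaches the given quantile across spots.
#'
#' @param comp Composition matrix.
#' @param celltype Target cell-type column name.
#' @param quantile_cut Quantile cutoff (default 0.9, i.e. the top decile).
#' @return Character vector of spot ids.
#' @export
top_target_spots <- function(comp, celltype, quantile_cut = 0.9) {
  if (!celltype %in% colnames(comp))
    stop_coloc("data_error", sprintf("cell type '%s' not in composition", celltype))
  thr <- quantile(comp[, celltype], quantile_cut)
  rownames(comp)[comp[, celltype] >= thr]
}

#' Validate and normalize a pipeline run configuration
#'
#' Accepts a YAML/JSON file path or an equivalent named list, checks it, and
#' fills defaults: k grid 5..50 in steps of 5, delta threshold 0.05,
#' n_perm 1000, argmax identity rule, Spearman correlation. The result is a
#' fixed point: `validate_config(validate_config(x))` returns the same
#' config. All violations are reported together.
#'
#' @param x Path to a YAML or JSON config, or a named list.
#' @return A normalized `run_config` list.
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else yaml::read_yaml(x)
  }
  if (inherits(x, "run_config")) x <- unclass(x)
  if (!is.list(x)) stop_coloc("config_error", "config must be a file path or a named list")
  bad <- character()
  unknown <- setdiff(names(x), CONFIG_KEYS)
  if (length(unknown))
    bad <- c(bad, paste("unknown config keys:", paste(unknown, collapse = ", ")))
  has_files <- !is.null(x[["inputs"]])
  has_synth <- !is.null(x[["synthetic"]])
  if (!has_files && !has_synth)
    bad <- c(bad, "either 'inputs' (spots, composition paths) or 'synthetic' is required")
  if (has_files && !all(c("spots", "composition") %in% names(x[["inputs"]])))
    bad <- c(bad, "'inputs' needs 'spots' and 'composition' paths")
  cfg <- list(
    inputs = x[["inputs"]],
    synthetic = x[["synthetic"]],
    target = x[["target"]] %||% if (has_synth) "target" else NULL,
    response = x[["response"]] %||% if (has_synth) "response" else NULL,
    k_min = x[["k_min"]] %||% 5L, k_max = x[["k_max"]] %||% 50L,
    k_step = x[["k_step"]] %||% 5L,
    delta_threshold = x[["delta_threshold"]] %||% 0.05,
    n_perm = x[["n_perm"]] %||% 1000L,
    identity_rule = x[["identity_rule"]] %||% "argmax",
    tau = x[["tau"]], tau_quantile = x[["tau_quantile"]],
    target_selection = x[["target_selection"]] %||% "identity",
    moran_k = x[["moran_k"]], moran_n_perm = x[["moran_n_perm"]] %||% 999L,
    correlation_method = x[["correlation_method"]] %||% "spearman",
    seed = x[["seed"]] %||% 1L,
    outdir = x[["outdir"]] %||% "coloc_run"
  )
  if (is.null(cfg$target) || is.null(cfg$response))
    bad <- c(bad, "'target' and 'response' cell-type names are required for file inputs")
  if (cfg$k_min > cfg$k_max || cfg$k_step < 1)
    bad <- c(bad, "k grid must satisfy k_min <= k_max and k_step >= 1")
  if (cfg$n_perm < 1) bad <- c(bad, "n_perm must be >= 1")
  if (!cfg$identity_rule %in% c("argmax", "threshold"))
    bad <- c(bad, "identity_rule must be 'argmax' or 'threshold'")
  if (cfg$identity_rule == "threshold" && is.null(cfg$tau) && is.null(cfg$tau_quantile))
    bad <- c(bad, "threshold rule needs 'tau' or 'tau_quantile'")
  if (!cfg$target_selection %in% c("identity", "top_quantile"))
    bad <- c(bad, "target_selection must be 'identity' or 'top_quantile'")
  if (cfg$target_selection == "top_quantile" && is.null(cfg$tau_quantile))
    cfg$tau_quantile <- 0.9
  if (!cfg$correlation_method %in% c("spearman", "pearson"))
    bad <- c(bad, "correlation_method must be 'spearman' or 'pearson'")
  if (has_synth) {
    cfg$synthetic <- tryCatch(
      unclass(do.call(synthetic_config,
                      c(x[["synthetic"]][setdiff(names(x[["synthetic"]]), "seed")],
                        list(seed = x[["synthetic"]][["seed"]] %||% cfg$seed)))),
      error = function(e) { bad <<- c(bad, conditionMessage(e)); x[["synthetic"]] }
    )
  }
  if (length(bad)) stop_coloc("config_error", paste(bad, collapse = "\n"))
  structure(cfg, class = "run_config")
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stop_coloc("pipeline_error",
               sprintf("pipeline aborted at stage '%s': %s (partial outputs kept)",
                       stage, conditionMessage(e)))
  })
}

#' Run the full co-localization pipeline
#'
#' Fixed stage order: load-or-simulate -> spot identity -> k scan and
#' stable-k selection -> permutation test at k* -> global Moran's I on the
#' response field -> target-response spatial correlation. Every intermediate
#' (spot table, composition, identity calls, enrichment curve, null means)
#' is written under `config$outdir`, and the final report is both a JSON
#' record and a human-readable summary. Reruns with the same config are
#' byte-identical.
#'
#' Moran's I defaults its neighbourhood size to the selected k*, but never
#' to a fallback k*: when no stable interval exists the curve's fallback
#' flag is set, and Moran falls back to the smallest grid k unless
#' `moran_k` is given explicitly.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @return A `run_report` list (invisibly also written to
#'   `outdir/report.json` and `outdir/summary.txt`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)

  dat <- run_stage("load_data", {
    if (!is.null(cfg$synthetic)) {
      sc <- do.call(synthetic_config, cfg$synthetic)
      spots <- generate_spots(sc)
      gen <- generate_composition(spots, sc)
      write.csv(gen$truth, out("latent_fields_truth.csv"), row.names = FALSE, quote = FALSE)
      list(spots = spots, comp = gen$composition)
    } else {
      spots <- read_spot_table(cfg$inputs$spots)
      if (!is.null(spots$sample) && length(unique(spots$sample)) > 1)
        stop_coloc("data_error",
                   "multi-sample spot table: run the pipeline per sample section")
      list(spots = spots, comp = read_composition(cfg$inputs$composition))
    }
  })
  spots <- dat$spots
  comp <- validate_composition(dat$comp, spots)
  comp <- comp[match(spots$spot_id, rownames(comp)), , drop = FALSE]
  for (ct in c(cfg$target, cfg$response)) {
    if (!ct %in% colnames(comp))
      stop_coloc("config_error", sprintf("cell type '%s' is not a composition column", ct))
  }
  write_spot_table(spots, out("spots.csv"))
  write_composition(comp, out("composition.csv"))

  identity <- run_stage("spot_identity", {
    tau <- cfg$tau
    if (cfg$identity_rule == "threshold" && is.null(tau))
      tau <- unname(quantile(comp[, cfg$target], cfg$tau_quantile))
    id <- call_spot_identity(comp, cfg$identity_rule, tau = tau)
    write.csv(data.frame(spot_id = names(id), label = as.character(id)),
              out("spot_identity.csv"), row.names = FALSE, quote = FALSE)
    id
  })
  targets <- if (cfg$target_selection == "top_quantile")
    top_target_spots(comp, cfg$target, cfg$tau_quantile)
  else names(identity)[!is.na(identity) & identity == cfg$target]
  if (length(targets) == 0)
    stop_coloc("degenerate_statistic",
               sprintf("no spot is assigned to target cell type '%s'", cfg$target))

  curve <- run_stage("scan_k", {
    cv <- scan_k(comp, spots, targets, cfg$response,
                 k_grid = seq(cfg$k_min, cfg$k_max, cfg$k_step),
                 n_perm = cfg$n_perm, delta_threshold = cfg$delta_threshold,
                 seed = cfg$seed)
    write_enrichment_curve(cv, out("enrichment_curve.tsv"))
    cv
  })

  permtest <- run_stage("permutation_test", {
    g <- build_knn(spots, curve$k_star)
    pt <- permutation_test(comp, g, targets, cfg$response, n_perm = cfg$n_perm,
                           seed = stage_seed(cfg$seed, "final_permtest"))
    write.csv(data.frame(null_mean = pt$null_means), out("null_means.csv"),
              row.names = FALSE, quote = FALSE)
    write_json_result(pt, out("permutation_test.json"))
    pt
  })

  moran <- run_stage("morans_i", {
    mk <- cfg$moran_k %||% if (curve$fallback) cfg$k_min else curve$k_star
    mr <- morans_i(spots, comp[, cfg$response], k_weights = mk,
                   n_perm = cfg$moran_n_perm, seed = stage_seed(cfg$seed, "moran"))
    write_json_result(mr, out("moran.json"))
    mr
  })

  correlation <- run_stage("spatial_correlation", {
    spatial_correlation(comp[, cfg$target], comp[, cfg$response],
                        method = cfg$correlation_method)
  })

  report <- structure(list(
    package_version = as.character(packageVersion("spotcoloc")),
    config = unclass(cfg),
    n_spots = nrow(spots), n_targets = length(targets),
    enrichment_curve = list(k = curve$k_grid, E = curve$E, delta = curve$delta,
                            stable_start = curve$stable_start,
                            stable_end = curve$stable_end,
                            k_star = curve$k_star, fallback = curve$fallback),
    permutation_test = as_record(permtest),
    moran = as_record(moran),
    correlation = unclass(correlation)
  ), class = "run_report")
  jsonlite::write_json(lapply(unclass(report), function(z) z),
                       out("report.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  writeLines(format_report(report), out("summary.txt"))
  invisible(report)
}

format_report <- function(r) {
  c(sprintf("spotcoloc %s run: %d spots, %d target spots", r$package_version,
            r$n_spots, r$n_targets),
    sprintf("k scan: %s", paste(sprintf("E(%d)=%.3f", r$enrichment_curve$k,
                                        r$enrichment_curve$E), collapse = " ")),
    if (isTRUE(r$enrichment_curve$fallback))
      sprintf("NO stable k interval; FALLBACK k* = %d (global peak E)",
              r$enrichment_curve$k_star)
    else
      sprintf("stable k interval [%d, %d], k* = %d", r$enrichment_curve$stable_start,
              r$enrichment_curve$stable_end, r$enrichment_curve$k_star),
    sprintf("permutation test at k*: E = %.4f, one-sided p = %.4g (n_perm = %d)",
            r$permutation_test$E, r$permutation_test$p_value, r$permutation_test$n_perm),
    sprintf("Moran's I (response field, k = %d): I = %.4f, p = %.4g",
            r$moran$k_weights, r$moran$I, r$moran$p_value),
    sprintf("target-response %s correlation: R = %.4f, p = %.4g",
            r$correlation$method, r$correlation$R, r$correlation$p_value))
}

#' @export
print.run_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
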