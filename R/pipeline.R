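# End-to-end orchestration: simulate/load a cohort, compute per-subject
# metrics and routing costs, normalize against null ensembles, and run the
# brain-behaviour statistics. All stages write plain CSVs so each is
# independently re-runnable; all randomness flows from the single config
# seed through named substreams.

#' Analysis run configuration
#'
#' @param input_dir Directory holding per-subject connectome TSVs and
#'   `phenotypes.csv`, or `NULL` to simulate.
#' @param simulate A [cohort_spec()] used when `input_dir` is `NULL`.
#' @param network `"hub-attached"`, `"whole-brain"` or `"both"`.
#' @param mode Metric mode, `"weighted"` or `"binary"`.
#' @param transform Weight-to-length transform.
#' @param grid_preset `"consistent"` or `"printed"`, see [lambda_grid()].
#' @param windows `"auto"` (data-driven from normalized curves) or
#'   `"fixed"` (the closed intervals `[-5.1, 0.15]` for transmission and
#'   `[-0.14, 2.76]` for information).
#' @param reading_regions Character vector of reading-network labels, or
#'   `NULL` for the packaged default.
#' @param hubs `"per-subject"` or a fixed character vector of hub labels.
#' @param degree_threshold Hub degree cut-off.
#' @param min_streamlines Edge threshold.
#' @param n_null Null-ensemble members per subject (0 skips normalization;
#'   required for `windows = "auto"`).
#' @param n_perm Permutations for the family-wise correction.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `run_config` list (all fields defaulted).
#' @export
run_config <- function(input_dir = NULL, simulate = cohort_spec(),
                       network = c("hub-attached", "whole-brain", "both"),
                       mode = c("weighted", "binary"),
                       transform = c("reciprocal", "neglog"),
                       grid_preset = c("consistent", "printed"),
                       windows = c("auto", "fixed"),
                       reading_regions = NULL,
                       hubs = "per-subject",
                       degree_threshold = 20,
                       min_streamlines = 3,
                       n_null = 50, n_perm = 1000, seed = 1L,
                       out_dir = tempfile("thalroute-run-")) {
  structure(list(
    input_dir = input_dir, simulate = simulate,
    network = match.arg(network), mode = match.arg(mode),
    transform = match.arg(transform),
    grid_preset = match.arg(grid_preset), windows = match.arg(windows),
    reading_regions = reading_regions, hubs = hubs,
    degree_threshold = degree_threshold,
    min_streamlines = min_streamlines,
    n_null = n_null, n_perm = n_perm, seed = seed, out_dir = out_dir
  ), class = "run_config")
}

fixed_windows <- function() {
  list(trans = c(-5.1, 0.15), info = c(-0.14, 2.76))
}

labels_or_file <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) readLines(x)
  else x
}

config_network_definition <- function(x, config) {
  labels <- node_labels(x)
  reading <- labels_or_file(config$reading_regions) %||% {
    if (all(reading_network_labels() %in% labels)) reading_network_labels()
    else unique(c(labels[seq_len(min(6, length(labels) - 1))],
                  labels[length(labels)]))
  }
  pivot <- if ("THA.L" %in% reading) "THA.L" else reading[length(reading)]
  hub_set <- if (identical(config$hubs, "per-subject")) {
    identify_hubs(x, config$degree_threshold)
  } else {
    labels_or_file(config$hubs)
  }
  network_definition(reading, hub_set, pivot)
}

subject_cost_scalars <- function(xt, nd, config, grid, seed) {
  nets <- if (config$network == "both") c("hub-attached", "whole-brain")
          else config$network
  purrr::map_dfr(nets, function(net) {
    xn <- if (net == "hub-attached") hub_attached_subnetwork(xt, nd) else xt
    spec <- suppressMessages(
      cost_spectrum(xn, pivot_pairs(nd), grid, config$transform))
    tc <- thalamic_cost(spec, nd)
    ncs <- NULL
    wins <- if (config$windows == "fixed" || config$n_null == 0) {
      fixed_windows()
    } else {
      ens <- null_ensemble(xn, config$n_null, seed = seed)
      ncs <- suppressMessages(
        normalized_cost_curves(xn, ens, pivot_pairs(nd), grid,
                               config$transform))
      w_t <- suppressWarnings(efficient_lambda_window(ncs, "trans"))
      w_i <- suppressWarnings(efficient_lambda_window(ncs, "info"))
      list(trans = if (length(w_t)) w_t else fixed_windows()$trans,
           info = if (length(w_i)) w_i else fixed_windows()$info)
    }
    if (!is.null(ncs)) {
      ncs <- ncs |>
        dplyr::mutate(in_window_trans = .data$ln_lambda %in% wins$trans,
                      in_window_info = .data$ln_lambda %in% wins$info)
    }
    tibble::tibble(
      subject_id = xt$subject_id,
      network = net,
      c_thal_trans = window_average_cost(
        dplyr::filter(tc, .data$cost == "trans"), wins$trans, "total"),
      c_thal_info = window_average_cost(
        dplyr::filter(tc, .data$cost == "info"), wins$info, "total"),
      spectrum = list(tc),
      pair_spectrum = list(tibble::as_tibble(spec)),
      normalized = list(ncs)
    )
  })
}

#' Run the metric stage
#'
#' Simulates or loads a cohort, thresholds each connectome, computes nodal
#' metrics (degree, strength, CC, LE) and pivot-aggregated routing costs on
#' the configured network(s), and writes `nodal_metrics.csv`,
#' `thalamic_costs.csv`, the per-lambda `cost_curves.csv`, the merged
#' `analysis_table.csv`, and `config.json` into the output directory.
#' Per-subject failures are quarantined with their reasons in
#' `quarantine.csv`; the run fails only if every subject fails.
#'
#' @param config A [run_config()].
#' @return The analysis table (one row per subject), invisibly writing all
#'   stage outputs.
#' @export
run_metrics <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$input_dir)) {
    sim_spec <- config$simulate
    sim_spec$seed <- derive_seed(config$seed, "simulate")
    cohort <- generate_cohort(sim_spec)
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
    data <- list(connectomes = cohort$connectomes,
                 phenotypes = cohort$phenotypes)
  } else {
    data <- read_cohort(config$input_dir)
  }
  pheno <- data$phenotypes
  need <- c("subject_id", "age_years", "sex", "handedness")
  miss <- setdiff(need, names(pheno))
  if (length(miss) > 0) {
    stop("phenotype table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  grid <- lambda_grid(config$grid_preset)
  results <- purrr::imap(data$connectomes, function(x, id) {
    tryCatch({
      xt <- threshold_edges(x, config$min_streamlines)
      nd <- config_network_definition(xt, config)
      sub <- hub_attached_subnetwork(xt, nd)
      nm <- dplyr::bind_rows(
        node_metrics(xt, config$mode, "whole-brain"),
        node_metrics(sub, config$mode, "hub-attached"))
      costs <- subject_cost_scalars(
        xt, nd, config, grid, seed = derive_seed(config$seed,
                                                 paste0("nulls-", id)))
      fa <- if (!is.null(x$fa)) mean_edge_fa(sub) else NA_real_
      list(ok = TRUE, id = id, metrics = nm, costs = costs, mean_fa = fa,
           pivot = nd$pivot_node)
    }, error = function(e) list(ok = FALSE, id = id,
                                reason = conditionMessage(e)))
  })
  failed <- purrr::keep(results, ~ !.x$ok)
  if (length(failed) > 0) {
    quarantine <- tibble::tibble(
      subject_id = purrr::map_chr(failed, "id"),
      reason = purrr::map_chr(failed, "reason"))
    readr::write_csv(quarantine, file.path(config$out_dir, "quarantine.csv"))
    warning(nrow(quarantine), " subject(s) quarantined", call. = FALSE)
  }
  ok <- purrr::keep(results, "ok")
  if (length(ok) == 0) stop("all subjects failed; see quarantine.csv")
  nodal <- purrr::map_dfr(ok, "metrics")
  readr::write_csv(nodal, file.path(config$out_dir, "nodal_metrics.csv"))
  cost_rows <- purrr::map_dfr(ok, "costs")
  curves <- cost_rows |>
    dplyr::mutate(curve = purrr::map(.data$spectrum, function(tc) {
      dplyr::select(tibble::as_tibble(tc), -dplyr::any_of("subject_id"))
    })) |>
    dplyr::select("subject_id", "network", "curve") |>
    tidyr::unnest("curve")
  readr::write_csv(curves, file.path(config$out_dir, "cost_curves.csv"))
  spectra <- cost_rows |>
    dplyr::mutate(curve = purrr::map(.data$pair_spectrum, function(sp) {
      dplyr::select(sp, -dplyr::any_of("subject_id"))
    })) |>
    dplyr::select("subject_id", "network", "curve") |>
    tidyr::unnest("curve")
  readr::write_csv(spectra, file.path(config$out_dir, "cost_spectra.csv"))
  norm_rows <- cost_rows |>
    dplyr::filter(!purrr::map_lgl(.data$normalized, is.null))
  if (nrow(norm_rows) > 0) {
    norm_csv <- norm_rows |>
      dplyr::mutate(curve = purrr::map(.data$normalized,
                                       tibble::as_tibble)) |>
      dplyr::select("subject_id", "network", "curve") |>
      tidyr::unnest("curve")
    readr::write_csv(norm_csv,
                     file.path(config$out_dir, "normalized_curves.csv"))
  }
  scalars <- dplyr::select(cost_rows, -"spectrum", -"pair_spectrum",
                           -"normalized")
  readr::write_csv(scalars, file.path(config$out_dir, "thalamic_costs.csv"))
  pivots <- purrr::map_chr(ok, "pivot")
  pivot_metrics <- nodal |>
    dplyr::filter(.data$network == "hub-attached",
                  .data$node == pivots[match(.data$subject_id,
                                             purrr::map_chr(ok, "id"))]) |>
    dplyr::select("subject_id", "cc", "le", "degree", "strength")
  # the pipeline-computed metrics are canonical; drop phenotype columns
  # (e.g. a simulated cohort's planted target metric) that would clash
  analysis <- pheno |>
    dplyr::select(-dplyr::any_of(c("cc", "le", "degree", "strength",
                                   "c_thal_trans", "c_thal_info"))) |>
    dplyr::inner_join(pivot_metrics, by = "subject_id") |>
    dplyr::inner_join(
      scalars |>
        dplyr::filter(.data$network ==
                        ifelse(config$network == "both", "hub-attached",
                               config$network)) |>
        dplyr::select("subject_id", "c_thal_trans", "c_thal_info"),
      by = "subject_id")
  if (!"mean_fa" %in% names(analysis)) {
    analysis$mean_fa <- purrr::map_dbl(ok, "mean_fa")
  }
  readr::write_csv(analysis, file.path(config$out_dir, "analysis_table.csv"))
  cfg <- config
  cfg$simulate <- unclass(cfg$simulate)
  jsonlite::write_json(
    purrr::discard(unclass(cfg), is.null),
    file.path(config$out_dir, "config.json"), auto_unbox = TRUE)
  writeLines(c(
    sprintf("master seed: %d", config$seed),
    sprintf("simulation sub-seed: %d", derive_seed(config$seed, "simulate")),
    sprintf("null-ensemble sub-seeds: nulls-<subject_id> from master"),
    sprintf("permutation sub-seed: %d",
            derive_seed(config$seed, "permutations")),
    sprintf("edge threshold: %d streamlines", config$min_streamlines),
    sprintf("hub threshold: degree > %d", config$degree_threshold),
    sprintf("grid preset: %s; windows: %s; null members: %d",
            config$grid_preset, config$windows, config$n_null),
    sprintf("metric mode: %s; length transform: %s", config$mode,
            config$transform),
    sprintf("subjects analyzed: %d; quarantined: %d", length(ok),
            length(failed))
  ), file.path(config$out_dir, "log.txt"))
  invisible(analysis)
}

#' Run the statistics stage
#'
#' Reads `analysis_table.csv` from the configured output directory, runs
#' permutation-corrected partial correlations between the network metrics
#' and the reading scores, and a hierarchical regression ladder (Model 1:
#' covariates; Model 2: + CC and LE; Model 3: + transmission and
#' informational cost). Writes `correlations.csv`, `regression.csv` and a
#' plain-text `report.txt`.
#'
#' @param config A [run_config()] whose metric stage has run.
#' @param response Outcome for the regression ladder (default `"pde_std"`).
#' @return List with `correlations` (a `stat_report`) and `ladder` (a
#'   `regression_ladder`).
#' @export
run_stats <- function(config, response = "pde_std") {
  stopifnot(inherits(config, "run_config"))
  path <- file.path(config$out_dir, "analysis_table.csv")
  if (!file.exists(path)) stop("run_metrics() must run first: missing ", path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  metrics <- intersect(c("cc", "le", "c_thal_trans", "c_thal_info"),
                       names(tab))
  metrics <- metrics[vapply(metrics, function(m) {
    v <- stats::sd(tab[[m]])
    if (!is.finite(v) || v < 1e-12) {
      warning("metric ", m, " has zero variance; excluded", call. = FALSE)
      FALSE
    } else TRUE
  }, logical(1))]
  scores <- intersect(c("swe_std", "pde_std", "pc_std",
                        "ran_items_per_sec"), names(tab))
  report <- permutation_fwe(tab, metrics, scores, n_perm = config$n_perm,
                            seed = derive_seed(config$seed, "permutations"))
  readr::write_csv(tidy(report),
                   file.path(config$out_dir, "correlations.csv"))
  covs <- covariate_set(response, tab)
  blocks <- list(
    "Model 1" = covs,
    "Model 2" = intersect(c("cc", "le"), metrics),
    "Model 3" = intersect(c("c_thal_trans", "c_thal_info"), metrics))
  blocks <- purrr::keep(blocks, ~ length(.x) > 0)
  ladder <- hierarchical_regression(tab, response, blocks)
  readr::write_csv(tidy(ladder), file.path(config$out_dir, "regression.csv"))
  rpt <- c(
    sprintf("Partial correlations (%d permutations, seed %d)",
            config$n_perm, config$seed),
    utils::capture.output(print(as.data.frame(tidy(report)))),
    "",
    sprintf("Hierarchical regression: response %s", response),
    sprintf("%-10s %8s %8s %8s %8s", "", "R2", "dR2", "F", "p"),
    sprintf("%-10s %8.3f %8.3f %8.2f %8.3f", ladder$model,
            ladder$r.squared, ladder$delta.r.squared, ladder$f.change,
            ladder$p.change))
  writeLines(rpt, file.path(config$out_dir, "report.txt"))
  list(correlations = report, ladder = ladder)
}
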