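# End-to-end orchestration: prune -> occurrences -> pseudo-absence candidates
# -> blocks/folds -> datasets -> fit sub-models -> evaluate -> thresholds ->
# ensemble maps.

#' Pipeline run configuration
#'
#' Defaults are the method's canonical settings: correlation cutoff 0.8,
#' geographic exclusion at 2 degrees, PA1 of 20,000, three replicates, six
#' folds from four blocks, 500-tree forests, MaxTSS thresholds.
#'
#' @param collinearity_cutoff prune predictors with pairwise `|r|` above this.
#' @param pa_method `"geographic"` or `"sre"` pseudo-absence candidates.
#' @param min_degrees exclusion radius for the geographic method.
#' @param n_pa1 PA1 sample size per replicate.
#' @param n_replicates number of replicates.
#' @param algorithm `"CT"`, `"RT"` or `"both"`.
#' @param threshold_method one of [THRESHOLD_METHODS].
#' @param n_trees trees per forest.
#' @param tolerance pairwise-distance-sampling tolerance.
#' @param distance `"haversine"` or `"degrees"` for distance matching.
#' @param accuracy_floor optional minimum test ROC AUC; sub-models below it
#'   are excluded from the ensembles (default `NULL` = keep all).
#' @param swap_heldout swap the test/threshold roles of held-out blocks.
#' @param seed master seed.
#' @return a `sdm_config` list.
#' @export
sdm_config <- function(collinearity_cutoff = 0.8,
                       pa_method = c("geographic", "sre"),
                       min_degrees = 2.0, n_pa1 = 20000, n_replicates = 3,
                       algorithm = c("both", "CT", "RT"),
                       threshold_method = "max_tss", n_trees = 500,
                       tolerance = 0.33,
                       distance = c("haversine", "degrees"),
                       accuracy_floor = NULL, swap_heldout = FALSE, seed = 1) {
  structure(
    list(
      collinearity_cutoff = collinearity_cutoff,
      pa_method = match.arg(pa_method), min_degrees = min_degrees,
      n_pa1 = n_pa1, n_replicates = n_replicates,
      algorithm = match.arg(algorithm), threshold_method = threshold_method,
      n_trees = n_trees, tolerance = tolerance,
      distance = match.arg(distance), accuracy_floor = accuracy_floor,
      swap_heldout = swap_heldout, seed = seed
    ),
    class = "sdm_config"
  )
}

#' Run the full presence-only random-forest workflow
#'
#' Executes, in order: collinearity pruning of the stack; pseudo-absence
#' candidate generation; block partition and fold enumeration; assembly of
#' the `n_replicates x 6` sub-model datasets; per sub-model and algorithm a
#' random-forest fit, threshold-independent evaluation on its testing data,
#' threshold selection on its threshold-setting data, threshold-dependent
#' evaluation at the chosen threshold, and grid prediction; finally the
#' numeric (max then mean) and binary (any-of-6 then 2-of-3) ensembles per
#' algorithm.
#'
#' @param stack a `predictor_stack`.
#' @param occ an `occurrence_set` on the stack grid.
#' @param config a `sdm_config`.
#' @param output_dir optional directory; when given, grids (`.asc`), the
#'   sub-model table (CSV) and a JSON report are written there via
#'   [write_run_outputs()].
#' @return a `sdm_run` list: `config`, `kept_layers`, `correlations`,
#'   `partition`, `plan`, `submodels` (data frame: replicate, fold,
#'   algorithm, role sizes, all metrics, threshold), `ensembles` (per
#'   algorithm: `numeric`, `binary`, and per-sub-model grids), and
#'   `guidance` comparing CT vs RT when both ran.
#' @export
run_pipeline <- function(stack, occ, config = sdm_config(), output_dir = NULL) {
  algorithms <- if (config$algorithm == "both") c("CT", "RT") else config$algorithm

  kept <- stack$layer_names
  correlations <- NULL
  if (length(stack$layer_names) >= 2L) {
    correlations <- correlation_matrix(stack)
    kept <- prune_collinear(correlations, config$collinearity_cutoff)
  }
  stack2 <- if (identical(kept, stack$layer_names)) stack else subset_stack(stack, kept)

  mask <- switch(config$pa_method,
    geographic = geographic_candidates(stack2, occ, config$min_degrees),
    sre = sre_candidates(stack2, occ)
  )
  partition <- partition_blocks(occ)
  plan <- enumerate_folds(partition, swap_heldout = config$swap_heldout)
  datasets <- build_datasets(occ, partition, plan, mask, stack2,
    n_pa1 = config$n_pa1, n_replicates = config$n_replicates,
    seed = config$seed, tolerance = config$tolerance,
    distance = config$distance
  )

  rows <- list()
  grids <- list() # grids[[alg]][[replicate]][[fold]]
  bins <- list()
  for (alg in algorithms) {
    grids[[alg]] <- replicate(config$n_replicates, list(), simplify = FALSE)
    bins[[alg]] <- replicate(config$n_replicates, list(), simplify = FALSE)
    for (ds in datasets) {
      spec <- model_spec(alg,
        n_trees = config$n_trees,
        seed = config$seed + 10000L * ds$replicate_id + 100L * ds$fold_id
      )
      tr <- training_data(ds)
      model <- fit_rf(spec, tr$x, tr$label)

      te <- testing_data(ds)
      p_test <- predict_points(model, te$x)
      nm <- numeric_metrics(p_test, te$label)
      aucs <- auc_suite(p_test, te$label)

      th <- threshold_data(ds)
      p_thr <- predict_points(model, th$x)
      thr <- select_threshold(config$threshold_method, p_thr, th$label)
      tm <- confusion_metrics(confusion(p_test, te$label, thr$threshold))

      prov <- list(replicate_id = ds$replicate_id, fold_id = ds$fold_id,
        algorithm = alg)
      grid <- predict_grid(model, stack2, provenance = prov)
      grids[[alg]][[ds$replicate_id]][[length(grids[[alg]][[ds$replicate_id]]) + 1L]] <- grid
      bins[[alg]][[ds$replicate_id]][[length(bins[[alg]][[ds$replicate_id]]) + 1L]] <-
        binarize(grid, thr$threshold)

      rows[[length(rows) + 1L]] <- data.frame(
        replicate = ds$replicate_id, fold = ds$fold_id, algorithm = alg,
        n_train = length(tr$label), n_test = length(te$label),
        n_threshold = length(th$label),
        rmse = nm$rmse, mae = nm$mae, r2 = nm$r2, mxe = nm$mxe,
        auc_roc = aucs$auc_roc, auc_sens = aucs$auc_sens,
        auc_spec = aucs$auc_spec, auc_acc = aucs$auc_acc,
        threshold = thr$threshold, sensitivity = tm$sensitivity,
        specificity = tm$specificity, oa = tm$oa, kappa = tm$kappa,
        tss = tm$tss
      )
    }
  }
  submodels <- do.call(rbind, rows)

  ensembles <- list()
  for (alg in algorithms) {
    keep_grids <- grids[[alg]]
    keep_bins <- bins[[alg]]
    n_sub <- length(keep_grids[[1]])
    if (!is.null(config$accuracy_floor)) {
      sub <- submodels[submodels$algorithm == alg, ]
      for (r in seq_along(keep_grids)) {
        ok <- sub$auc_roc[sub$replicate == r] >= config$accuracy_floor
        if (!any(ok)) {
          stop("accuracy floor ", config$accuracy_floor, " rejects every ",
            alg, " sub-model of replicate ", r,
            call. = FALSE
          )
        }
        if (!all(ok)) {
          message("ensemble: dropping ", sum(!ok), " ", alg,
            " sub-model(s) of replicate ", r, " below AUC ",
            config$accuracy_floor)
        }
        keep_grids[[r]] <- keep_grids[[r]][ok]
        keep_bins[[r]] <- keep_bins[[r]][ok]
      }
      n_sub <- NULL # arity intentionally relaxed after gating
    }
    ensembles[[alg]] <- list(
      numeric = numeric_ensemble(keep_grids,
        n_submodels = n_sub, n_replicates = config$n_replicates
      ),
      binary = binary_ensemble(keep_bins,
        n_submodels = n_sub, n_replicates = config$n_replicates,
        min_replicates = min(2, config$n_replicates)
      ),
      submodel_grids = grids[[alg]], submodel_binaries = bins[[alg]]
    )
  }

  guidance <- NULL
  if (length(algorithms) == 2L) {
    m <- stats::aggregate(
      submodels[, c("auc_roc", "rmse", "r2")],
      by = list(algorithm = submodels$algorithm), FUN = mean
    )
    ct <- m[m$algorithm == "CT", ]
    rt <- m[m$algorithm == "RT", ]
    guidance <- list(
      discrimination_winner = if (rt$auc_roc >= ct$auc_roc) "RT" else "CT",
      reliability_winner = if (ct$rmse <= rt$rmse) "CT" else "RT",
      mean_auc = stats::setNames(m$auc_roc, m$algorithm),
      mean_rmse = stats::setNames(m$rmse, m$algorithm),
      note = paste(
        "Prefer the discrimination winner when ranking sites matters most,",
        "the reliability winner when calibrated probabilities do."
      )
    )
  }

  run <- structure(
    list(
      config = config, kept_layers = kept, correlations = correlations,
      partition = partition, plan = plan, n_presences = occ$n,
      species_id = occ$species_id, submodels = submodels,
      ensembles = ensembles, guidance = guidance
    ),
    class = "sdm_run"
  )
  if (!is.null(output_dir)) write_run_outputs(run, output_dir)
  run
}

#' @export
print.sdm_run <- function(x, ...) {
  cat("sdm_run:", x$species_id, "-", nrow(x$submodels), "sub-model(s),",
    length(x$kept_layers), "predictor(s) kept\n")
  agg <- stats::aggregate(x$submodels$auc_roc,
    by = list(algorithm = x$submodels$algorithm), FUN = mean
  )
  for (i in seq_len(nrow(agg))) {
    cat("  mean test AUC", agg$algorithm[i], "=", round(agg$x[i], 3), "\n")
  }
  invisible(x)
}

#' Write the artifacts of a pipeline run
#'
#' Writes per-algorithm final and complete numeric/binary maps as `.asc`
#' grids, the sub-model metric table as CSV, and a JSON report (config, kept
#' layers, sub-model table, guidance). Rerunning with the same config and
#' seeds reproduces the report byte for byte.
#'
#' @param run an `sdm_run`.
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wg <- function(grid, name) {
    p <- file.path(dir, paste0(name, ".asc"))
    write_asc_grid(grid$values, grid$origin, grid$cell_size, p,
      nodata = if (inherits(grid, "binary_grid")) 255 else -9999
    )
    p
  }
  for (alg in names(run$ensembles)) {
    e <- run$ensembles[[alg]]
    paths <- c(paths, wg(e$numeric$final, paste0(tolower(alg), "_final_numeric")))
    paths <- c(paths, wg(e$binary$final, paste0(tolower(alg), "_final_binary")))
    for (r in seq_along(e$numeric$complete)) {
      paths <- c(paths, wg(e$numeric$complete[[r]],
        sprintf("%s_complete_numeric_rep%d", tolower(alg), r)))
      paths <- c(paths, wg(e$binary$complete[[r]],
        sprintf("%s_complete_binary_rep%d", tolower(alg), r)))
    }
  }
  csv <- file.path(dir, "submodel_metrics.csv")
  utils::write.csv(run$submodels, csv, row.names = FALSE)
  report <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(
      species_id = run$species_id, config = unclass(run$config),
      kept_layers = run$kept_layers, n_presences = run$n_presences,
      block_sizes = as.integer(tabulate(run$partition$block, 4)),
      submodels = run$submodels, guidance = run$guidance
    ),
    report,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(c(paths, csv, report))
}
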