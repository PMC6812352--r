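# Random-forest sub-models: the classification-tree (CT) vote-proportion and
# regression-tree (RT) average contracts over the randomForest learner.

#' Specify a random-forest sub-model
#'
#' CT treats presence/absence as two classes and reads the proportion of
#' trees voting "presence" as a relative index of occurrence; RT regresses on
#' the 0/1 labels and averages the tree outputs. Neither needs tuning here:
#' model outcomes are famously insensitive to these parameters, so the
#' learner's own defaults are kept (500 trees; `sqrt(p)` candidate features
#' per split for CT, `floor(p/3)` for RT).
#'
#' @param algorithm `"CT"` (classification) or `"RT"` (regression).
#' @param n_trees number of trees (default 500).
#' @param features_per_split `"default"` or an integer number of candidate
#'   predictors per split.
#' @param seed integer seed making the fit deterministic.
#' @return a `model_spec`.
#' @export
model_spec <- function(algorithm = c("CT", "RT"), n_trees = 500,
                       features_per_split = "default", seed = 1) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(n_trees) || n_trees < 1) stop("`n_trees` must be >= 1", call. = FALSE)
  if (!identical(features_per_split, "default") &&
    (!is.numeric(features_per_split) || features_per_split < 1)) {
    stop("`features_per_split` must be \"default\" or a positive integer", call. = FALSE)
  }
  structure(
    list(
      algorithm = algorithm, n_trees = as.integer(n_trees),
      features_per_split = features_per_split, seed = seed
    ),
    class = "model_spec"
  )
}

#' Fit a CT or RT random forest on labeled samples
#'
#' @param spec a `model_spec`.
#' @param x numeric predictor matrix with column names; no missing values.
#' @param label 0/1 vector (1 = presence); both labels must appear at least
#'   twice.
#' @return a `fitted_model` holding the spec, the predictor names and the
#'   underlying forest.
#' @export
fit_rf <- function(spec, x, label) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("`x` needs column names", call. = FALSE)
  if (anyNA(x)) stop("`x` contains missing predictor values", call. = FALSE)
  if (length(label) != nrow(x)) stop("label/row count mismatch", call. = FALSE)
  if (!all(label %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  if (min(table(factor(label, levels = c(0, 1)))) < 2) {
    stop("training data needs at least two samples of each label", call. = FALSE)
  }
  p <- ncol(x)
  mtry <- if (identical(spec$features_per_split, "default")) {
    if (spec$algorithm == "CT") max(1L, floor(sqrt(p))) else max(1L, floor(p / 3))
  } else {
    min(p, as.integer(spec$features_per_split))
  }
  forest <- with_seed(spec$seed, {
    if (spec$algorithm == "CT") {
      randomForest::randomForest(
        x = x, y = factor(label, levels = c(0, 1)),
        ntree = spec$n_trees, mtry = mtry
      )
    } else {
      # regressing on 0/1 labels is the point of the RT algorithm; silence the
      # learner's few-unique-values advisory for that intended use
      withCallingHandlers(
        randomForest::randomForest(
          x = x, y = as.numeric(label),
          ntree = spec$n_trees, mtry = mtry
        ),
        warning = function(w) {
          if (grepl("five or fewer unique values", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      )
    }
  })
  structure(
    list(spec = spec, predictor_names = colnames(x), forest = forest),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(
    "fitted_model:", x$spec$algorithm, "random forest,", x$spec$n_trees,
    "trees on", length(x$predictor_names), "predictor(s)\n"
  )
  invisible(x)
}

#' Predict suitability at sample points
#'
#' CT returns the fraction of trees voting presence (granularity
#' `1/n_trees`); RT returns the mean of the tree outputs. Both lie in
#' `[0, 1]` for 0/1 training labels.
#'
#' @param model a `fitted_model`.
#' @param x predictor matrix whose columns cover `model$predictor_names`.
#' @return numeric vector of suitabilities in `[0, 1]`.
#' @export
predict_points <- function(model, x) {
  stopifnot(inherits(model, "fitted_model"))
  x <- rbind(x)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(model$predictor_names)) {
      stop("prediction matrix has ", ncol(x), " columns; model expects ",
        length(model$predictor_names),
        call. = FALSE
      )
    }
    colnames(x) <- model$predictor_names
  }
  missing <- setdiff(model$predictor_names, colnames(x))
  if (length(missing)) {
    stop("prediction matrix lacks predictor(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  x <- x[, model$predictor_names, drop = FALSE]
  if (model$spec$algorithm == "CT") {
    as.numeric(stats::predict(model$forest, x, type = "prob")[, "1"])
  } else {
    as.numeric(stats::predict(model$forest, x))
  }
}

#' Predict suitability over the whole grid
#'
#' @param model a `fitted_model`.
#' @param stack a `predictor_stack` containing every model predictor.
#' @param provenance optional list recorded on the output grid.
#' @return a `suitability_grid` (see [numeric_ensemble()]); nodata cells stay
#'   `NA`.
#' @export
predict_grid <- function(model, stack, provenance = NULL) {
  missing <- setdiff(model$predictor_names, stack$layer_names)
  if (length(missing)) {
    stop("stack lacks predictor layer(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  cells <- valid_cells(stack)
  x <- extract_values(stack, cells, model$predictor_names)
  vals <- matrix(NA_real_, stack$n_rows, stack$n_cols)
  vals[cells] <- predict_points(model, x)
  suitability_grid(vals,
    origin = stack$origin, cell_size = stack$cell_size,
    provenance = provenance
  )
}
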