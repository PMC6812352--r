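# The eight threshold-setting methods and binary conversion of suitability
# grids.

#' Threshold-setting methods
#'
#' Tags accepted by [select_threshold()]. `max_tss` is the default of the
#' pipeline; `max_kappa`, `max_oa` and `min_rocdist` complete the group of
#' objective methods recommended for presence-only random-forest models.
#' @export
THRESHOLD_METHODS <- c(
  "default05", "meanprob", "predprev_obs", "sens_eq_spec",
  "max_oa", "min_rocdist", "max_kappa", "max_tss"
)

#' Select a classification threshold on threshold-setting data
#'
#' All data-driven methods optimize over the exhaustive candidate grid
#' `{0} U unique(p) U {1}` — every objective is a step function of the
#' threshold, so the grid contains an optimum — and break ties toward the
#' smallest threshold, making the selection deterministic. Methods:
#'
#' * `default05` — the fixed value 0.5.
#' * `meanprob` — mean predicted suitability of all threshold-setting
#'   observations (presences and pseudo-absences).
#' * `predprev_obs` — predicted prevalence (fraction of `p >= t`) closest to
#'   the observed prevalence.
#' * `sens_eq_spec` — minimize `|sensitivity - specificity|`.
#' * `max_oa`, `max_kappa`, `max_tss` — maximize overall accuracy, Kappa, or
#'   the true skill statistic.
#' * `min_rocdist` — minimize the distance
#'   `sqrt((1 - sens)^2 + (1 - spec)^2)` to the perfect corner of ROC space.
#'
#' @param method one of [THRESHOLD_METHODS].
#' @param p predicted suitabilities on the threshold-setting data.
#' @param o 0/1 observations (needed by the data-driven methods).
#' @return a `threshold_result`: `method`, `threshold`, `objective_value`
#'   (`NA` for the two methods with no objective).
#' @export
select_threshold <- function(method, p, o = NULL) {
  if (!method %in% THRESHOLD_METHODS) {
    stop("unknown threshold method '", method, "'; use one of: ",
      paste(THRESHOLD_METHODS, collapse = ", "),
      call. = FALSE
    )
  }
  res <- function(threshold, objective = NA_real_) {
    structure(
      list(method = method, threshold = threshold, objective_value = objective),
      class = "threshold_result"
    )
  }
  if (method == "default05") {
    return(res(0.5))
  }
  if (is.null(o)) stop("method '", method, "' needs observations `o`", call. = FALSE)
  check_sample(p, o)
  if (method == "meanprob") {
    return(res(mean(p)))
  }
  if (!any(o == 1) || !any(o == 0)) {
    stop("data-driven threshold methods need both classes present", call. = FALSE)
  }
  sw <- threshold_sweep(p, o)
  # ties are broken toward the smallest threshold; objectives equal within
  # 1e-12 count as tied so that mathematically tied candidates are not split
  # by floating-point evaluation order
  pick <- function(objective, maximize) {
    signed <- if (maximize) objective else -objective
    k <- which(signed >= max(signed) - 1e-12)[1]
    res(sw$threshold[k], objective[k])
  }
  n <- length(p)
  switch(method,
    predprev_obs = {
      predprev <- vapply(sw$threshold, function(t) mean(p >= t), numeric(1))
      pick(-abs(predprev - mean(o)), maximize = TRUE)
    },
    sens_eq_spec = pick(-abs(sw$sensitivity - sw$specificity), maximize = TRUE),
    max_oa = pick(sw$oa, maximize = TRUE),
    min_rocdist = pick(sqrt((1 - sw$sensitivity)^2 + (1 - sw$specificity)^2),
      maximize = FALSE),
    max_kappa = {
      kappa <- mapply(function(tp, fp, tn, fn) {
        confusion_metrics(list(TP = tp, FP = fp, TN = tn, FN = fn))$kappa
      }, sw$TP, sw$FP, sw$TN, sw$FN)
      kappa[is.na(kappa)] <- -Inf
      pick(kappa, maximize = TRUE)
    },
    max_tss = pick(sw$sensitivity + sw$specificity - 1, maximize = TRUE)
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("threshold_result:", x$method, "->", format(x$threshold), "\n")
  invisible(x)
}

#' Convert a suitability grid to a binary presence/absence grid
#'
#' @param grid a `suitability_grid`.
#' @param threshold classification threshold in `[0, 1]`; suitability
#'   `>= threshold` maps to 1.
#' @return a `binary_grid` with values 0/1 and `NA` on nodata cells.
#' @export
binarize <- function(grid, threshold) {
  stopifnot(inherits(grid, "suitability_grid"))
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]", call. = FALSE)
  vals <- ifelse(grid$values >= threshold, 1, 0)
  structure(
    list(
      values = vals, origin = grid$origin, cell_size = grid$cell_size,
      provenance = c(grid$provenance, list(threshold = threshold))
    ),
    class = "binary_grid"
  )
}
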