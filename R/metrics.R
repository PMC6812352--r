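# Accuracy measures: threshold-independent (RMSE, MAE, R^2, MXE, four AUCs)
# and threshold-dependent (sensitivity, specificity, OA, Kappa, TSS).

check_sample <- function(p, o) {
  if (length(p) != length(o)) stop("`p` and `o` differ in length", call. = FALSE)
  if (length(p) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("predictions must lie in [0, 1]", call. = FALSE)
  if (!all(o %in% c(0, 1))) stop("observations must be 0 or 1", call. = FALSE)
  invisible(TRUE)
}

#' Threshold-independent reliability metrics
#'
#' For predictions `p` against 0/1 observations `o` with prevalence
#' `q = mean(o)`:
#' `RMSE = sqrt(mean((p - o)^2))`; `MAE = mean(|p - o|)`;
#' `R2 = 1 - mean((p - o)^2) / (q (1 - q))` (the error of the
#' constant-prevalence predictor normalizes the score, so R2 is undefined —
#' returned `NA` — when only one class is present); `MXE` is the mean
#' negative log-likelihood, with predictions clamped to
#' `[1e-15, 1 - 1e-15]` so vote proportions of exactly 0 or 1 cannot
#' produce infinities.
#'
#' @param p numeric predictions in `[0, 1]`.
#' @param o 0/1 observations.
#' @return named list: `rmse`, `mae`, `r2`, `mxe`.
#' @export
numeric_metrics <- function(p, o) {
  check_sample(p, o)
  mse <- mean((p - o)^2)
  q <- mean(o)
  r2 <- if (q > 0 && q < 1) 1 - mse / (q * (1 - q)) else NA_real_
  pc <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  mxe <- -mean(ifelse(o == 1, log(pc), log(1 - pc)))
  list(rmse = sqrt(mse), mae = mean(abs(p - o)), r2 = r2, mxe = mxe)
}

#' ROC AUC (Mann-Whitney form)
#'
#' The probability that a random presence is ranked above a random absence,
#' ties counted one half.
#'
#' @inheritParams numeric_metrics
#' @return AUC in `[0, 1]`, `NA` if only one class is present.
#' @export
auc_roc <- function(p, o) {
  check_sample(p, o)
  n1 <- sum(o == 1)
  n0 <- sum(o == 0)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  r <- rank(p)
  (sum(r[o == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Areas under the threshold-response curves
#'
#' Sensitivity, specificity and overall accuracy are step functions of the
#' classification threshold `t` (predict presence iff `p >= t`); each is
#' integrated by the trapezoid rule over the exhaustive candidate grid
#' `{0} U unique(p) U {1}`, together with the ROC AUC.
#'
#' @inheritParams numeric_metrics
#' @return named list: `auc_roc`, `auc_sens`, `auc_spec`, `auc_acc`.
#' @export
auc_suite <- function(p, o) {
  check_sample(p, o)
  n1 <- sum(o == 1)
  n0 <- sum(o == 0)
  if (n1 == 0 || n0 == 0) {
    return(list(auc_roc = NA_real_, auc_sens = NA_real_,
      auc_spec = NA_real_, auc_acc = NA_real_))
  }
  sw <- threshold_sweep(p, o)
  list(
    auc_roc = auc_roc(p, o),
    auc_sens = trapezoid(sw$threshold, sw$sensitivity),
    auc_spec = trapezoid(sw$threshold, sw$specificity),
    auc_acc = trapezoid(sw$threshold, sw$oa)
  )
}

#' Confusion counts at a threshold, over the candidate threshold grid
#'
#' Shared sweep used by the AUC curves and the threshold-setting methods:
#' for each candidate `t` in the ascending grid `{0} U unique(p) U {1}`,
#' predictions `p >= t` count as presence.
#'
#' @inheritParams numeric_metrics
#' @return data frame: `threshold`, `TP`, `FP`, `TN`, `FN`, `sensitivity`,
#'   `specificity`, `oa`.
#' @export
threshold_sweep <- function(p, o) {
  check_sample(p, o)
  ts <- sort(unique(c(0, p, 1)))
  n1 <- sum(o == 1)
  n0 <- sum(o == 0)
  n <- n1 + n0
  tp <- vapply(ts, function(t) sum(p >= t & o == 1), numeric(1))
  fp <- vapply(ts, function(t) sum(p >= t & o == 0), numeric(1))
  data.frame(
    threshold = ts, TP = tp, FP = fp, TN = n0 - fp, FN = n1 - tp,
    sensitivity = if (n1) tp / n1 else NA_real_,
    specificity = if (n0) (n0 - fp) / n0 else NA_real_,
    oa = (tp + (n0 - fp)) / n
  )
}

#' Confusion matrix at one threshold
#'
#' @inheritParams numeric_metrics
#' @param threshold classification threshold in `[0, 1]`; `p >= threshold`
#'   predicts presence.
#' @return named list `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(p, o, threshold) {
  check_sample(p, o)
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]", call. = FALSE)
  pred <- p >= threshold
  list(
    TP = sum(pred & o == 1), FP = sum(pred & o == 0),
    TN = sum(!pred & o == 0), FN = sum(!pred & o == 1)
  )
}

#' Threshold-dependent accuracy measures from a confusion matrix
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `OA = (TP+TN)/n`, `TSS = sensitivity + specificity - 1`, and Cohen's
#' `Kappa = (OA - p_e)/(1 - p_e)` with chance agreement
#' `p_e = [(TP+FN)(TP+FP) + (TN+FP)(TN+FN)] / n^2`. Kappa is `NA` when
#' `p_e = 1` (all counts in one cell).
#'
#' @param cm list with `TP`, `FP`, `TN`, `FN` (e.g. from [confusion()]).
#' @return named list: `sensitivity`, `specificity`, `oa`, `kappa`, `tss`.
#' @export
confusion_metrics <- function(cm) {
  tp <- cm$TP
  fp <- cm$FP
  tn <- cm$TN
  fn <- cm$FN
  n <- tp + fp + tn + fn
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  oa <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps * 4) NA_real_ else (oa - pe) / (1 - pe)
  list(sensitivity = sens, specificity = spec, oa = oa, kappa = kappa,
    tss = sens + spec - 1)
}
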