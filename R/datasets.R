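# Assembly of the 6 folds x 3 replicates sub-model datasets with 1:1
# presence:pseudo-absence training balance and distance-matched evaluation
# absences.

role_set <- function(cells, coords, x, label) {
  list(cells = cells, coords = coords, x = x, label = rep(label, nrow(cells)))
}

#' Build the sub-model training / testing / threshold-setting datasets
#'
#' For each replicate an independent PA1 is drawn (seed `seed + replicate`).
#' For each fold: `MCp` are the presences of the two training blocks; `MCpa`
#' is a simple random sample of `|MCp|` PA1 cells (1:1 training balance);
#' `MVp` are the test-block presences and `MVpa` their pairwise-distance
#' matches from the remaining PA1; `TSp`/`TSpa` likewise for the
#' threshold-setting block, drawing from what PA1 leaves after `MCpa` and
#' `MVpa`. Test/threshold presences with no eligible match are dropped (with
#' a message) so every role stays exactly 1:1. The three absence sets of one
#' fold are pairwise disjoint by construction.
#'
#' @param occ an `occurrence_set`.
#' @param partition a `block_partition` of `occ`.
#' @param plan a `fold_plan`.
#' @param mask a `candidate_mask` of eligible pseudo-absence cells.
#' @param stack the (pruned) `predictor_stack` supplying predictor vectors.
#' @param n_pa1 PA1 size per replicate (default 20000).
#' @param n_replicates number of independent PA1 replicates (default 3).
#' @param seed master seed; replicate r uses `seed + r` for PA1 and
#'   `seed + 1000*r + fold` for the `MCpa` draw, so every dataset is
#'   independently reproducible.
#' @param tolerance pairwise-distance-sampling tolerance (default 0.33).
#' @param distance distance metric for matching: `"haversine"` or `"degrees"`.
#' @return list of `n_replicates * nrow(plan)` objects of class
#'   `submodel_dataset`, each with `replicate_id`, `fold_id`, `seed` and the
#'   six role sets `MCp`, `MCpa`, `MVp`, `MVpa`, `TSp`, `TSpa` (each holding
#'   `cells`, `coords`, `x`, `label`).
#' @export
build_datasets <- function(occ, partition, plan, mask, stack,
                           n_pa1 = 20000, n_replicates = 3, seed = 1,
                           tolerance = 0.33,
                           distance = c("haversine", "degrees")) {
  distance <- match.arg(distance)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  datasets <- list()
  for (r in seq_len(n_replicates)) {
    pa1 <- sample_pa1(mask, n = n_pa1, seed = seed + r)
    pa_x <- extract_values(stack, pa1$cells)
    for (f in seq_len(nrow(plan))) {
      fold <- plan[f, ]
      mcp_i <- which(partition$block %in% c(fold$train1, fold$train2))
      mvp_i <- which(partition$block == fold$test_block)
      tsp_i <- which(partition$block == fold$threshold_block)
      if (!length(mcp_i) || !length(mvp_i) || !length(tsp_i)) {
        stop("replicate ", r, ", fold ", f, ": an empty block leaves a role ",
          "with no presences",
          call. = FALSE
        )
      }
      n_mcp <- length(mcp_i)
      if (nrow(pa1$cells) < n_mcp) {
        stop("PA1 of ", nrow(pa1$cells), " is smaller than the ", n_mcp,
          " training presences of replicate ", r, ", fold ", f,
          call. = FALSE
        )
      }
      mcpa_sel <- with_seed(
        seed + 1000 * r + f,
        sample.int(nrow(pa1$cells), n_mcp)
      )
      avail <- setdiff(seq_len(nrow(pa1$cells)), mcpa_sel)

      mcp_coords <- partition$coords[mcp_i, , drop = FALSE]
      take_matched <- function(p_idx, avail_idx) {
        # match each presence to an unused PA1 cell at a comparable distance
        # from the training presences; unmatched presences are dropped
        m <- pwd_sample(
          partition$coords[p_idx, , drop = FALSE],
          pa1$coords[avail_idx, , drop = FALSE],
          mcp_coords,
          tolerance = tolerance, distance = distance
        )
        keep <- !is.na(m)
        list(p_idx = p_idx[keep], pa_idx = avail_idx[m[keep]])
      }
      mv <- take_matched(mvp_i, avail)
      avail2 <- setdiff(avail, mv$pa_idx)
      if (!length(avail2)) {
        stop("replicate ", r, ", fold ", f, ": PA1 exhausted before ",
          "threshold-setting absences could be drawn",
          call. = FALSE
        )
      }
      ts <- take_matched(tsp_i, avail2)
      if (!length(mv$p_idx) || !length(ts$p_idx)) {
        stop("replicate ", r, ", fold ", f, ": all test or threshold ",
          "presences left unmatched; fold degenerate",
          call. = FALSE
        )
      }

      p_role <- function(idx, label) {
        cells <- partition$cells[idx, , drop = FALSE]
        role_set(cells, partition$coords[idx, , drop = FALSE],
          extract_values(stack, cells), label)
      }
      pa_role <- function(idx, label) {
        role_set(pa1$cells[idx, , drop = FALSE],
          pa1$coords[idx, , drop = FALSE],
          pa_x[idx, , drop = FALSE], label)
      }
      datasets[[length(datasets) + 1L]] <- structure(
        list(
          replicate_id = r, fold_id = f, seed = seed,
          MCp = p_role(mcp_i, 1L), MCpa = pa_role(mcpa_sel, 0L),
          MVp = p_role(mv$p_idx, 1L), MVpa = pa_role(mv$pa_idx, 0L),
          TSp = p_role(ts$p_idx, 1L), TSpa = pa_role(ts$pa_idx, 0L)
        ),
        class = "submodel_dataset"
      )
    }
  }
  datasets
}

#' @export
print.submodel_dataset <- function(x, ...) {
  cat(
    "submodel_dataset: replicate", x$replicate_id, "fold", x$fold_id,
    "- train", nrow(x$MCp$cells), "+", nrow(x$MCpa$cells),
    "| test", nrow(x$MVp$cells), "+", nrow(x$MVpa$cells),
    "| threshold", nrow(x$TSp$cells), "+", nrow(x$TSpa$cells), "\n"
  )
  invisible(x)
}

role_pair <- function(ds, p, pa) {
  list(
    x = rbind(ds[[p]]$x, ds[[pa]]$x),
    label = c(ds[[p]]$label, ds[[pa]]$label)
  )
}

#' Labeled design matrices of one sub-model dataset
#'
#' @param ds a `submodel_dataset`.
#' @return list with `x` (predictor matrix) and `label` (1 = presence,
#'   0 = pseudo-absence); presences first.
#' @export
training_data <- function(ds) role_pair(ds, "MCp", "MCpa")

#' @rdname training_data
#' @export
testing_data <- function(ds) role_pair(ds, "MVp", "MVpa")

#' @rdname training_data
#' @export
threshold_data <- function(ds) role_pair(ds, "TSp", "TSpa")

#' Flatten a sub-model dataset to one data frame
#'
#' @param x a `submodel_dataset`.
#' @param ... unused.
#' @return data frame with columns `role`, `row`, `col`, `lon`, `lat`,
#'   `label`, then one column per predictor; suitable for `write.csv()`.
#' @export
as.data.frame.submodel_dataset <- function(x, ...) {
  roles <- c("MCp", "MCpa", "MVp", "MVpa", "TSp", "TSpa")
  do.call(rbind, lapply(roles, function(r) {
    rs <- x[[r]]
    data.frame(
      role = r, row = rs$cells[, 1], col = rs$cells[, 2],
      lon = rs$coords[, 1], lat = rs$coords[, 2], label = rs$label,
      rs$x, row.names = NULL, check.names = FALSE
    )
  }))
}
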