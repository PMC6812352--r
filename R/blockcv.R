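# Spatial block cross-validation: four geographic blocks and the six
# training-pair folds.

#' Partition presence cells into four geographic blocks
#'
#' The presence extent is split at the midpoint of its longitudinal range (the
#' dividing meridian); each half is then split at the midpoint of its own
#' presence latitudinal range (its dividing parallel). A cell goes west when
#' `lon < meridian` and north when `lat >= parallel`, making the partition
#' deterministic. Block ids: 1 west-north, 2 west-south, 3 east-north,
#' 4 east-south. Splitting on equal extent (not equal counts) keeps the
#' blocks geographically contiguous and non-overlapping, which is the point
#' of block cross-validation: spatial separation of training and evaluation
#' data.
#'
#' @param occ an `occurrence_set` with at least 4 cells spanning nonzero
#'   longitude and latitude extent.
#' @return a `block_partition`: `block` (integer vector, one id in 1..4 per
#'   presence cell), `cells`, `coords`, `meridian`,
#'   `parallels` (named: west, east).
#' @export
partition_blocks <- function(occ) {
  if (occ$n < 4L) stop("need at least 4 presence cells to form blocks", call. = FALSE)
  lon <- occ$coords[, 1]
  lat <- occ$coords[, 2]
  if (diff(range(lon)) == 0 || diff(range(lat)) == 0) {
    stop("presences span zero longitudinal or latitudinal extent; blocks degenerate",
      call. = FALSE
    )
  }
  meridian <- mean(range(lon))
  west <- lon < meridian
  parallel_w <- mean(range(lat[west]))
  parallel_e <- mean(range(lat[!west]))
  block <- integer(occ$n)
  block[west & lat >= parallel_w] <- 1L
  block[west & lat < parallel_w] <- 2L
  block[!west & lat >= parallel_e] <- 3L
  block[!west & lat < parallel_e] <- 4L
  structure(
    list(
      block = block, cells = occ$cells, coords = occ$coords,
      meridian = meridian,
      parallels = c(west = parallel_w, east = parallel_e)
    ),
    class = "block_partition"
  )
}

#' @export
print.block_partition <- function(x, ...) {
  cat("block_partition: sizes", paste(tabulate(x$block, 4), collapse = "/"),
    "at meridian", format(x$meridian), "\n")
  invisible(x)
}

#' Enumerate the six training-pair folds
#'
#' Every unordered pair of the four blocks serves once as training data; of
#' the two held-out blocks, the lower id tests the model and the higher id
#' sets the threshold (swap with `swap_heldout = TRUE`). The pairs are listed
#' in lexicographic order, so each block trains in exactly three folds.
#'
#' @param partition a `block_partition` (only validity is checked; the plan
#'   depends on the block ids alone).
#' @param swap_heldout if `TRUE`, the higher-id held-out block tests and the
#'   lower sets the threshold.
#' @return a `fold_plan` data frame: `fold_id`, `train1`, `train2`,
#'   `test_block`, `threshold_block` (6 rows).
#' @export
enumerate_folds <- function(partition, swap_heldout = FALSE) {
  if (!inherits(partition, "block_partition")) {
    stop("`partition` must come from partition_blocks()", call. = FALSE)
  }
  pairs <- t(utils::combn(4L, 2L))
  heldout <- t(apply(pairs, 1, function(p) setdiff(1:4, p)))
  test <- if (swap_heldout) heldout[, 2] else heldout[, 1]
  thresh <- if (swap_heldout) heldout[, 1] else heldout[, 2]
  plan <- data.frame(
    fold_id = seq_len(nrow(pairs)),
    train1 = pairs[, 1], train2 = pairs[, 2],
    test_block = test, threshold_block = thresh
  )
  class(plan) <- c("fold_plan", "data.frame")
  plan
}
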