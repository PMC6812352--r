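# Pseudo-absence candidate generation (geographic exclusion / surface range
# envelope), PA1 sampling, and pairwise distance sampling of matched absences.

new_candidate_mask <- function(method_tag, eligible, stack) {
  structure(
    list(
      method_tag = method_tag, eligible = eligible,
      origin = stack$origin, cell_size = stack$cell_size,
      n_rows = stack$n_rows, n_cols = stack$n_cols
    ),
    class = "candidate_mask"
  )
}

#' @export
print.candidate_mask <- function(x, ...) {
  cat(
    "candidate_mask (", x$method_tag, "): ", sum(x$eligible),
    " eligible cell(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Geographic-exclusion pseudo-absence candidates
#'
#' A valid cell is an eligible pseudo-absence candidate when its center lies
#' at least `min_degrees` from the nearest presence cell center. The working
#' assumption is that sites far from every known presence are the most likely
#' to be genuinely unsuitable. Distance is Euclidean in degree space by
#' default; `metric = "chebyshev"` instead requires max(|dlon|, |dlat|) >=
#' `min_degrees`, the reading under which a point must be two whole degrees
#' away in latitude *or* longitude.
#'
#' @param stack a `predictor_stack`.
#' @param occ an `occurrence_set` on the same grid.
#' @param min_degrees exclusion radius in degrees (default 2, the classic
#'   "2 degrees" rule).
#' @param metric `"euclidean"` (default) or `"chebyshev"`.
#' @return a `candidate_mask` with `method_tag = "geographic"`.
#' @export
geographic_candidates <- function(stack, occ, min_degrees = 2,
                                  metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  if (!is.numeric(min_degrees) || min_degrees <= 0) {
    stop("`min_degrees` must be positive", call. = FALSE)
  }
  cells <- valid_cells(stack)
  centers <- cell_centers(stack, cells)
  d <- min_dist_to(centers, occ$coords,
    distance = if (metric == "euclidean") "degrees" else "chebyshev"
  )
  eligible <- matrix(FALSE, stack$n_rows, stack$n_cols)
  eligible[cells[d >= min_degrees, , drop = FALSE]] <- TRUE
  eligible[occ$cells] <- FALSE
  if (!any(eligible)) {
    stop("no eligible pseudo-absence cells at min_degrees = ", min_degrees,
      "; reduce the exclusion distance or enlarge the study extent",
      call. = FALSE
    )
  }
  new_candidate_mask("geographic", eligible, stack)
}

#' Surface-range-envelope pseudo-absence candidates
#'
#' The envelope is the closed per-layer `[min, max]` interval of predictor
#' values over the presence cells; cells with every layer inside every
#' interval are deemed climatically suitable, and the remaining valid cells —
#' at least one layer strictly outside its envelope — are "potential"
#' absences. Presence cells are never eligible (they sit inside their own
#' envelope by construction).
#'
#' @param stack a `predictor_stack`.
#' @param occ an `occurrence_set` on the same grid.
#' @return a `candidate_mask` with `method_tag = "sre"`.
#' @export
sre_candidates <- function(stack, occ) {
  xp <- extract_values(stack, occ$cells)
  lo <- apply(xp, 2, min)
  hi <- apply(xp, 2, max)
  cells <- valid_cells(stack)
  x <- extract_values(stack, cells)
  outside <- rep(FALSE, nrow(x))
  for (j in seq_len(ncol(x))) {
    outside <- outside | x[, j] < lo[j] | x[, j] > hi[j]
  }
  eligible <- matrix(FALSE, stack$n_rows, stack$n_cols)
  eligible[cells[outside, , drop = FALSE]] <- TRUE
  eligible[occ$cells] <- FALSE
  if (!any(eligible)) {
    stop("surface range envelope covers every valid cell; no candidate absences",
      call. = FALSE
    )
  }
  new_candidate_mask("sre", eligible, stack)
}

#' Draw the initial pseudo-absence sample (PA1)
#'
#' Uniform sample without replacement from the eligible cells. When fewer
#' than `n` candidates exist, all of them are taken with a warning.
#'
#' @param mask a `candidate_mask`.
#' @param n target sample size (default 20000).
#' @param seed integer seed; the draw is reproducible and leaves the caller's
#'   RNG state untouched.
#' @return a `pa_sample`: `cells` (row, col), `coords` (lon/lat centers),
#'   `seed`, `method_tag`.
#' @export
sample_pa1 <- function(mask, n = 20000, seed = 1) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  idx <- which(mask$eligible, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  n_avail <- nrow(idx)
  if (n_avail == 0L) stop("candidate mask has no eligible cells", call. = FALSE)
  if (n_avail < n) {
    warning("only ", n_avail, " eligible cells for a requested PA1 of ", n,
      "; taking all of them",
      call. = FALSE
    )
  }
  take <- min(n, n_avail)
  sel <- with_seed(seed, sample.int(n_avail, take))
  cells <- idx[sel, , drop = FALSE]
  structure(
    list(
      cells = cells,
      coords = cbind(
        lon = mask$origin[1] + (cells[, 2] - 0.5) * mask$cell_size,
        lat = mask$origin[2] - (cells[, 1] - 0.5) * mask$cell_size
      ),
      seed = seed, method_tag = mask$method_tag
    ),
    class = "pa_sample"
  )
}

#' Pairwise distance sampling of matched pseudo-absences
#'
#' Removes spatial sorting bias from evaluation data: each fixed (test or
#' threshold-setting) presence, taken in input order, is matched to an unused
#' candidate whose distance to the nearest reference (training) presence is
#' close to the presence's own. A candidate with nearest-reference distance
#' `d_s` is eligible for a presence with distance `d_f` when
#' `|d_s - d_f| <= tolerance * d_f`; among eligible unused candidates the one
#' minimizing `|d_s - d_f|` is taken. Presences with no eligible candidate
#' remain unmatched.
#'
#' @param fixed_xy (lon, lat) matrix of presences needing matches.
#' @param candidate_xy (lon, lat) matrix of candidate pseudo-absences.
#' @param reference_xy (lon, lat) matrix of reference (training) presences.
#' @param tolerance relative distance tolerance (default 0.33, the
#'   convention of the pairwise-distance-sampling method).
#' @param distance `"haversine"` (great-circle, default) or `"degrees"`.
#' @return integer vector, one element per fixed presence: the matched row
#'   index into `candidate_xy`, or `NA` when unmatched.
#' @export
pwd_sample <- function(fixed_xy, candidate_xy, reference_xy, tolerance = 0.33,
                       distance = c("haversine", "degrees")) {
  distance <- match.arg(distance)
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("`tolerance` must be positive", call. = FALSE)
  }
  fixed_xy <- as.matrix(fixed_xy)
  candidate_xy <- as.matrix(candidate_xy)
  reference_xy <- as.matrix(reference_xy)
  if (!nrow(fixed_xy) || !nrow(candidate_xy) || !nrow(reference_xy)) {
    stop("all point sets must be nonempty", call. = FALSE)
  }
  d_f <- min_dist_to(fixed_xy, reference_xy, distance)
  d_s <- min_dist_to(candidate_xy, reference_xy, distance)
  used <- rep(FALSE, nrow(candidate_xy))
  match_idx <- rep(NA_integer_, nrow(fixed_xy))
  for (i in seq_len(nrow(fixed_xy))) {
    gap <- abs(d_s - d_f[i])
    ok <- !used & gap <= tolerance * d_f[i]
    if (any(ok)) {
      j <- which(ok)[which.min(gap[ok])]
      match_idx[i] <- j
      used[j] <- TRUE
    }
  }
  if (anyNA(match_idx)) {
    message("pwd_sample: ", sum(is.na(match_idx)), " of ", nrow(fixed_xy),
      " presence(s) left unmatched")
  }
  match_idx
}
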