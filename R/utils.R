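# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral of y over x (x ascending)
#' @noRd
trapezoid <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Minimum distance from each point to a set of reference points.
#'
#' Points are (lon, lat) matrices. `distance` is one of "haversine" (metres,
#' great-circle), "degrees" (Euclidean in degree space) or "chebyshev"
#' (max of |dlon|, |dlat|).
#' @noRd
min_dist_to <- function(points, refs, distance = "haversine") {
  points <- as.matrix(points)
  refs <- as.matrix(refs)
  d <- rep(Inf, nrow(points))
  for (i in seq_len(nrow(refs))) {
    di <- switch(distance,
      haversine = geosphere::distHaversine(points, refs[i, , drop = FALSE]),
      degrees = sqrt((points[, 1] - refs[i, 1])^2 + (points[, 2] - refs[i, 2])^2),
      chebyshev = pmax(abs(points[, 1] - refs[i, 1]), abs(points[, 2] - refs[i, 2])),
      stop("unknown distance metric: ", distance, call. = FALSE)
    )
    d <- pmin(d, di)
  }
  d
}
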