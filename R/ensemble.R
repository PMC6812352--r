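# Ensemble combination of sub-model predictions: per-replicate "complete"
# maps and the final map across replicates.

#' Construct a suitability grid
#'
#' @param values numeric matrix in `[0, 1]` on valid cells, `NA` = nodata.
#' @param origin (lon, lat) of the top-left corner.
#' @param cell_size cell edge in degrees.
#' @param provenance optional list describing where the grid came from.
#' @return object of class `suitability_grid`.
#' @export
suitability_grid <- function(values, origin, cell_size, provenance = NULL) {
  rng <- range(values, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(values = values, origin = origin, cell_size = cell_size,
      provenance = provenance),
    class = "suitability_grid"
  )
}

#' @export
print.suitability_grid <- function(x, ...) {
  cat("suitability_grid:", nrow(x$values), "x", ncol(x$values), "cells\n")
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size, tolerance = 1e-9))
}

check_groups <- function(groups, n_submodels, n_replicates, what) {
  if (!is.null(n_replicates) && length(groups) != n_replicates) {
    stop("expected ", n_replicates, " replicate group(s) of ", what, ", got ",
      length(groups),
      call. = FALSE
    )
  }
  ref <- groups[[1]][[1]]
  for (g in seq_along(groups)) {
    if (!is.null(n_submodels) && length(groups[[g]]) != n_submodels) {
      stop("replicate ", g, " holds ", length(groups[[g]]), " sub-model grid(s); ",
        "expected ", n_submodels,
        call. = FALSE
      )
    }
    for (grid in groups[[g]]) {
      if (!same_geometry(grid, ref)) {
        stop("misaligned grids in replicate ", g, call. = FALSE)
      }
    }
  }
  ref
}

#' Numeric ensemble: max over sub-models, mean over replicates
#'
#' Each replicate's "complete" map takes, cell by cell, the maximum of its
#' sub-model suitabilities (trusting each sub-model most where it is most
#' confident, under the assumption that all sub-models are acceptably
#' accurate); the final map is the cellwise mean of the complete maps.
#' Nodata propagates: a cell missing in any input is missing in the outputs.
#'
#' @param groups list of replicate groups, each a list of `suitability_grid`s
#'   (6 sub-models x 3 replicates at the design defaults).
#' @param n_submodels,n_replicates expected arity, checked unless `NULL`.
#' @return list with `complete` (one `suitability_grid` per replicate) and
#'   `final` (one `suitability_grid`).
#' @export
numeric_ensemble <- function(groups, n_submodels = 6, n_replicates = 3) {
  ref <- check_groups(groups, n_submodels, n_replicates, "suitability")
  complete <- lapply(seq_along(groups), function(g) {
    vals <- Reduce(pmax, lapply(groups[[g]], `[[`, "values"))
    suitability_grid(vals, ref$origin, ref$cell_size,
      provenance = list(stage = "complete", replicate_id = g)
    )
  })
  final_vals <- Reduce(`+`, lapply(complete, `[[`, "values")) / length(complete)
  list(
    complete = complete,
    final = suitability_grid(final_vals, ref$origin, ref$cell_size,
      provenance = list(stage = "final")
    )
  )
}

#' Binary ensemble: any-of-submodels, majority-of-replicates
#'
#' A replicate's complete binary map marks a cell present when at least one
#' of its sub-models does; the final map marks a cell present when at least
#' `min_replicates` complete maps do (2 of 3 at the design defaults).
#'
#' @param groups list of replicate groups, each a list of `binary_grid`s.
#' @param n_submodels,n_replicates expected arity, checked unless `NULL`.
#' @param min_replicates minimum number of agreeing complete maps (default 2).
#' @return list with `complete` (one `binary_grid` per replicate) and `final`.
#' @export
binary_ensemble <- function(groups, n_submodels = 6, n_replicates = 3,
                            min_replicates = 2) {
  ref <- check_groups(groups, n_submodels, n_replicates, "binary")
  complete <- lapply(seq_along(groups), function(g) {
    vals <- Reduce(pmax, lapply(groups[[g]], `[[`, "values"))
    structure(
      list(values = vals, origin = ref$origin, cell_size = ref$cell_size,
        provenance = list(stage = "complete", replicate_id = g)),
      class = "binary_grid"
    )
  })
  votes <- Reduce(`+`, lapply(complete, `[[`, "values"))
  final_vals <- ifelse(votes >= min_replicates, 1, 0)
  list(
    complete = complete,
    final = structure(
      list(values = final_vals, origin = ref$origin, cell_size = ref$cell_size,
        provenance = list(stage = "final", min_replicates = min_replicates)),
      class = "binary_grid"
    )
  )
}
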