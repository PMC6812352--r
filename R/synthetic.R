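# Synthetic predictor stacks and virtual species with a known suitability
# surface, so every pipeline stage is testable without external data.

running_mean <- function(v, r) {
  n <- length(v)
  cs <- cumsum(v)
  hi <- pmin(seq_len(n) + r, n)
  lo <- pmax(seq_len(n) - r, 1L)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

smooth_matrix <- function(m, r) {
  if (r < 1) {
    return(m)
  }
  m <- apply(m, 2, running_mean, r = r) # down columns
  t(apply(m, 1, running_mean, r = r)) # along rows
}

#' Generate a synthetic environmental predictor stack
#'
#' Each layer starts as standard-normal white noise, is smoothed with a
#' separable moving-average window of radius `round(smoothing)` cells —
#' giving the spatial autocorrelation real climate fields have — and is then
#' standardized to mean 0, sd 1 over the grid. Requested collinear pairs
#' `(j, k, r)` rebuild layer `k` as
#' `r * layer_j + sqrt(1 - r^2) * independent`, so its expected correlation
#' with layer `j` is `r`.
#'
#' @param n_layers number of layers (>= 1).
#' @param n_rows,n_cols grid dimensions.
#' @param smoothing moving-average radius in cells (0 = white noise).
#' @param collinear_pairs list of numeric triples `c(j, k, r_target)` with
#'   1-based layer indices `j != k`.
#' @param origin (lon, lat) of the top-left corner.
#' @param cell_size cell edge in degrees.
#' @param seed integer seed; identical seeds give identical stacks.
#' @return a `predictor_stack` with layers named `env_01`, `env_02`, ...
#' @export
generate_stack <- function(n_layers = 5, n_rows = 60, n_cols = 60,
                           smoothing = 3, collinear_pairs = NULL,
                           origin = c(100, 45), cell_size = 0.5, seed = 1) {
  if (n_layers < 1) stop("`n_layers` must be >= 1", call. = FALSE)
  if (smoothing < 0) stop("`smoothing` must be >= 0", call. = FALSE)
  r <- as.integer(round(smoothing))
  layers <- with_seed(seed, {
    raw <- lapply(seq_len(n_layers), function(i) {
      smooth_matrix(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols), r)
    })
    raw <- lapply(raw, function(m) (m - mean(m)) / stats::sd(m))
    for (pair in collinear_pairs) {
      if (length(pair) != 3 || pair[1] < 1 || pair[1] > n_layers ||
        pair[2] < 1 || pair[2] > n_layers || pair[1] == pair[2] ||
        abs(pair[3]) > 1) {
        stop("collinear pair must be c(j, k, r) with valid distinct layer ",
          "indices and |r| <= 1",
          call. = FALSE
        )
      }
      j <- pair[1]
      k <- pair[2]
      rt <- pair[3]
      indep <- smooth_matrix(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols), r)
      indep <- (indep - mean(indep)) / stats::sd(indep)
      m <- rt * raw[[j]] + sqrt(1 - rt^2) * indep
      raw[[k]] <- (m - mean(m)) / stats::sd(m)
    }
    raw
  })
  names(layers) <- sprintf("env_%02d", seq_len(n_layers))
  predictor_stack(layers, origin = origin, cell_size = cell_size)
}

#' Create a virtual species with a known logistic suitability surface
#'
#' True suitability is `s(x) = plogis(b0 + sum(b_j x_j))` over the stack
#' layers; presences are `n_presences` distinct valid cells sampled without
#' replacement with probability proportional to `s`. The returned truth
#' surface is what downstream predictions can be validated against — the
#' luxury real species never afford.
#'
#' @param stack a `predictor_stack`.
#' @param coefficients numeric vector `c(b0, b_1, ..., b_p)`: intercept then
#'   one slope per stack layer.
#' @param n_presences number of presence cells to draw.
#' @param seed integer seed.
#' @param species_id identifier for the occurrence set.
#' @return list with `species` (class `virtual_species`: `coefficients`,
#'   `true_suitability` as a `suitability_grid`, `n_presences`, `seed`) and
#'   `occurrences` (an `occurrence_set`).
#' @export
make_virtual_species <- function(stack, coefficients, n_presences, seed = 1,
                                 species_id = "virtual") {
  p <- length(stack$layer_names)
  if (length(coefficients) != p + 1L) {
    stop("need ", p + 1L, " coefficients (intercept + one per layer), got ",
      length(coefficients),
      call. = FALSE
    )
  }
  cells <- valid_cells(stack)
  if (n_presences < 1 || n_presences > nrow(cells)) {
    stop("`n_presences` must be between 1 and the ", nrow(cells),
      " valid cells",
      call. = FALSE
    )
  }
  x <- extract_values(stack, cells)
  eta <- coefficients[1] + as.numeric(x %*% coefficients[-1])
  s <- stats::plogis(eta)
  vals <- matrix(NA_real_, stack$n_rows, stack$n_cols)
  vals[cells] <- s
  sel <- with_seed(seed, sample.int(nrow(cells), n_presences, prob = s))
  pres <- cells[sel, , drop = FALSE]
  list(
    species = structure(
      list(
        coefficients = coefficients,
        true_suitability = suitability_grid(vals, stack$origin, stack$cell_size,
          provenance = list(stage = "truth")
        ),
        n_presences = n_presences, seed = seed
      ),
      class = "virtual_species"
    ),
    occurrences = new_occurrence_set(species_id, pres, cell_centers(stack, pres))
  )
}

#' Write a synthetic fixture to disk
#'
#' Emits one `.asc` grid per predictor layer, the true-suitability grid,
#' a presence CSV (`species_id, lon, lat`) and a JSON manifest, so a full
#' model run can start from files alone.
#'
#' @param dir output directory (created if needed).
#' @param stack a `predictor_stack`.
#' @param species a `virtual_species`.
#' @param occ the matching `occurrence_set`.
#' @return invisible list of written paths.
#' @export
write_fixture <- function(dir, stack, species, occ) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layer_paths <- file.path(dir, paste0(stack$layer_names, ".asc"))
  for (i in seq_along(stack$layer_names)) {
    write_asc_grid(stack$layers[[i]], stack$origin, stack$cell_size, layer_paths[i])
  }
  truth_path <- file.path(dir, "true_suitability.asc")
  write_asc_grid(species$true_suitability$values, stack$origin, stack$cell_size,
    truth_path)
  occ_path <- file.path(dir, "presences.csv")
  utils::write.csv(
    data.frame(species_id = occ$species_id, lon = occ$coords[, 1], lat = occ$coords[, 2]),
    occ_path,
    row.names = FALSE
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(
      layers = basename(layer_paths), truth = basename(truth_path),
      presences = basename(occ_path),
      coefficients = species$coefficients, n_presences = species$n_presences,
      seed = species$seed,
      grid = list(
        n_rows = stack$n_rows, n_cols = stack$n_cols,
        origin = stack$origin, cell_size = stack$cell_size
      )
    ),
    manifest_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(list(
    layers = layer_paths, truth = truth_path, presences = occ_path,
    manifest = manifest_path
  ))
}
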