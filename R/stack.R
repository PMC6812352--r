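# Environmental predictor stack: construction, plain-text raster I/O,
# correlation and collinearity pruning.

#' Build a predictor stack from aligned layer matrices
#'
#' A predictor stack holds one or more co-registered environmental layers on a
#' single geographic (lon/lat) grid. Rows run north to south; row 1 is the
#' northern edge. Cells where *any* layer is missing are masked out of every
#' layer (union-of-nodata rule), so all layers share one validity mask.
#'
#' @param layers named list of numeric matrices of identical dimension;
#'   `NA` marks nodata.
#' @param origin numeric length-2: (lon, lat) of the top-left grid corner.
#' @param cell_size positive cell edge length in decimal degrees.
#' @param crs_label free-text label of the coordinate system; the package
#'   assumes geographic lon/lat throughout.
#' @return an object of class `predictor_stack` with elements `layer_names`,
#'   `layers` (list of matrices with the shared mask applied), `mask` (logical
#'   matrix, `TRUE` = valid), `origin`, `cell_size`, `n_rows`, `n_cols`,
#'   `crs_label`.
#' @examples
#' st <- predictor_stack(
#'   list(temp = matrix(rnorm(100), 10), prec = matrix(rnorm(100), 10)),
#'   origin = c(100, 40), cell_size = 0.5
#' )
#' st$layer_names
#' @export
predictor_stack <- function(layers, origin, cell_size,
                            crs_label = "geographic lon/lat (WGS84)") {
  if (!is.list(layers) || length(layers) < 1L) {
    stop("`layers` must be a nonempty named list of matrices", call. = FALSE)
  }
  nms <- names(layers)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop("layer names must be present and unique", call. = FALSE)
  }
  dims <- lapply(layers, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("every layer must be a matrix", call. = FALSE)
  }
  d1 <- dims[[1]]
  for (i in seq_along(dims)) {
    if (!identical(dims[[i]], d1)) {
      stop("layer '", nms[i], "' has dimensions ", paste(dims[[i]], collapse = "x"),
        ", expected ", paste(d1, collapse = "x"),
        call. = FALSE
      )
    }
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a positive number", call. = FALSE)
  }
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("`origin` must be numeric (lon, lat) of the top-left corner", call. = FALSE)
  }
  layers <- lapply(layers, function(m) {
    storage.mode(m) <- "double"
    m
  })
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  layers <- lapply(layers, function(m) {
    m[!mask] <- NA_real_
    m
  })
  structure(
    list(
      layer_names = nms, layers = layers, mask = mask,
      origin = as.numeric(origin), cell_size = cell_size,
      n_rows = d1[1], n_cols = d1[2], crs_label = crs_label
    ),
    class = "predictor_stack"
  )
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(
    "predictor_stack:", length(x$layer_names), "layer(s),",
    x$n_rows, "x", x$n_cols, "cells of", x$cell_size, "deg\n"
  )
  cat("  layers:", paste(x$layer_names, collapse = ", "), "\n")
  cat("  valid cells:", sum(x$mask), "of", length(x$mask), "\n")
  invisible(x)
}

#' Longitude/latitude of cell centers
#'
#' @param stack a `predictor_stack` (or anything with `origin`, `cell_size`).
#' @param cells two-column integer matrix of (row, col), 1-based.
#' @return two-column matrix `lon`, `lat` of cell centers.
#' @export
cell_centers <- function(stack, cells) {
  cells <- rbind(cells) # tolerate a single (row, col) vector
  s <- stack$cell_size
  cbind(
    lon = stack$origin[1] + (cells[, 2] - 0.5) * s,
    lat = stack$origin[2] - (cells[, 1] - 0.5) * s
  )
}

#' Map points to the grid cells containing them
#'
#' Cell (r, c) covers lon in `[left, right)` and lat in `(bottom, top]`, so a
#' point on a shared edge belongs to the south/east neighbour (floor
#' convention from the top-left origin). Points outside the grid get `NA`.
#'
#' @param stack a `predictor_stack`.
#' @param lon,lat numeric vectors of point coordinates.
#' @return two-column integer matrix (row, col), `NA` rows for outside points.
#' @export
points_to_cells <- function(stack, lon, lat) {
  s <- stack$cell_size
  col <- floor((lon - stack$origin[1]) / s) + 1L
  row <- floor((stack$origin[2] - lat) / s) + 1L
  bad <- row < 1L | row > stack$n_rows | col < 1L | col > stack$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract predictor value vectors at cells
#'
#' @param stack a `predictor_stack`.
#' @param cells two-column (row, col) matrix.
#' @param layer_names layers to extract, default all, in stack order.
#' @return numeric matrix, one row per cell, one column per layer.
#' @export
extract_values <- function(stack, cells, layer_names = stack$layer_names) {
  cells <- rbind(cells)
  missing <- setdiff(layer_names, stack$layer_names)
  if (length(missing)) {
    stop("layer(s) not in stack: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- cbind(cells[, 1], cells[, 2])
  out <- vapply(
    layer_names, function(nm) stack$layers[[nm]][idx],
    numeric(nrow(cells))
  )
  out <- matrix(out, nrow = nrow(cells), dimnames = list(NULL, layer_names))
  out
}

#' All valid (non-nodata) cells of a stack
#' @param stack a `predictor_stack`.
#' @return two-column (row, col) integer matrix.
#' @export
valid_cells <- function(stack) {
  w <- which(stack$mask, arr.ind = TRUE)
  colnames(w) <- c("row", "col")
  w
}

#' Keep a subset of layers
#' @param stack a `predictor_stack`.
#' @param layer_names character vector of layers to keep, in the given order.
#' @return a new `predictor_stack`.
#' @export
subset_stack <- function(stack, layer_names) {
  missing <- setdiff(layer_names, stack$layer_names)
  if (length(missing)) {
    stop("layer(s) not in stack: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  predictor_stack(stack$layers[layer_names],
    origin = stack$origin,
    cell_size = stack$cell_size, crs_label = stack$crs_label
  )
}

# ---- plain-text raster I/O (ESRI ASCII grid) --------------------------------

#' Read a single-band ESRI ASCII grid (.asc)
#'
#' The ASCII grid is the plain-text raster interchange format understood by
#' every mainstream GIS; one header (ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value) followed by rows from north to south.
#'
#' @param path file path.
#' @return list with `values` (numeric matrix, `NA` = nodata), `origin`
#'   (top-left lon, lat), `cell_size`.
#' @export
read_asc_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster file: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr))) {
    stop("file ", path, " is not an ESRI ASCII grid (missing header keys)", call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(path, skip = length(hdr), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("file ", path, ": expected ", hdr$ncols * hdr$nrows, " values, got ", length(vals),
      call. = FALSE
    )
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(
    values = m,
    origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
    cell_size = hdr$cellsize
  )
}

#' Write a matrix as an ESRI ASCII grid (.asc)
#'
#' @param values numeric matrix (row 1 = north edge), `NA` written as `nodata`.
#' @param origin (lon, lat) of the top-left corner.
#' @param cell_size cell edge in degrees.
#' @param path output file path.
#' @param nodata nodata sentinel written to file.
#' @return `path`, invisibly.
#' @export
write_asc_grid <- function(values, origin, cell_size, path, nodata = -9999) {
  nr <- nrow(values)
  nc <- ncol(values)
  hdr <- c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(origin[1], digits = 15)),
    paste("yllcorner", format(origin[2] - nr * cell_size, digits = 15)),
    paste("cellsize", format(cell_size, digits = 15)),
    paste("NODATA_value", nodata)
  )
  vals <- values
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1, function(r) paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Load a predictor stack from single-band raster files
#'
#' Layers are validated to share one grid geometry (origin, cell size,
#' dimensions); resampling is deliberately out of scope — inputs must be
#' pre-aligned. The union of the per-layer nodata masks is applied everywhere.
#'
#' @param paths character vector of `.asc` file paths, one band each.
#' @param layer_names names for the layers; defaults to file basenames.
#' @return a `predictor_stack`, layers in the order given.
#' @export
load_stack <- function(paths, layer_names = NULL) {
  if (length(paths) < 1L) stop("need at least one raster path", call. = FALSE)
  if (is.null(layer_names)) {
    layer_names <- sub("\\.[^.]*$", "", basename(paths))
  }
  rasters <- lapply(paths, read_asc_grid)
  ref <- rasters[[1]]
  for (i in seq_along(rasters)) {
    r <- rasters[[i]]
    if (!isTRUE(all.equal(r$cell_size, ref$cell_size, tolerance = 1e-9)) ||
      !isTRUE(all.equal(r$origin, ref$origin, tolerance = 1e-9)) ||
      !identical(dim(r$values), dim(ref$values))) {
      stop("raster '", layer_names[i], "' is not aligned with '", layer_names[1],
        "' (origin/cell size/dimensions differ)",
        call. = FALSE
      )
    }
  }
  layers <- stats::setNames(lapply(rasters, `[[`, "values"), layer_names)
  predictor_stack(layers, origin = ref$origin, cell_size = ref$cell_size)
}

# ---- collinearity -----------------------------------------------------------

#' Pairwise Pearson correlation matrix over jointly valid cells
#'
#' @param stack a `predictor_stack` with at least two layers and at least
#'   three jointly valid cells.
#' @return square symmetric correlation matrix with layer names as dimnames
#'   (unit diagonal). Export with [utils::write.csv()] if needed.
#' @export
correlation_matrix <- function(stack) {
  if (length(stack$layer_names) < 2L) {
    stop("need at least two layers to correlate", call. = FALSE)
  }
  cells <- valid_cells(stack)
  if (nrow(cells) < 3L) stop("need at least 3 jointly valid cells", call. = FALSE)
  x <- extract_values(stack, cells)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("layer '", stack$layer_names[which(sds == 0)[1]],
      "' is constant over valid cells; correlation undefined",
      call. = FALSE
    )
  }
  stats::cor(x)
}

#' Greedy pruning of collinear predictors
#'
#' While any pair of retained layers has `|r| > cutoff`, the most correlated
#' pair is found and the member with the larger mean absolute correlation to
#' all other retained layers is dropped (ties drop the later-listed name).
#' This is deterministic for a fixed layer order, and the result contains no
#' pair above the cutoff. Absolute correlation is used throughout: strong
#' negative collinearity is as harmful as positive.
#'
#' @param corr square symmetric correlation matrix with dimnames
#'   (e.g. from [correlation_matrix()]).
#' @param cutoff retention cutoff in `(0, 1]`; layers in a pair with
#'   `|r| > cutoff` cannot both be kept. Default 0.8.
#' @return character vector of kept layer names, in original order.
#' @export
prune_collinear <- function(corr, cutoff = 0.8) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1) {
    stop("`cutoff` must lie in (0, 1]", call. = FALSE)
  }
  corr <- as.matrix(corr)
  nms <- colnames(corr)
  if (is.null(nms) || !identical(nms, rownames(corr))) {
    stop("`corr` must have matching row/column names", call. = FALSE)
  }
  if (max(abs(corr - t(corr))) > 1e-12) {
    stop("`corr` is not symmetric", call. = FALSE)
  }
  keep <- seq_along(nms)
  repeat {
    a <- abs(corr[keep, keep, drop = FALSE])
    diag(a) <- 0
    if (length(keep) < 2L || max(a) <= cutoff) break
    # worst pair first; which() is column-major so ties resolve deterministically
    w <- which(a == max(a), arr.ind = TRUE)[1, ]
    i <- keep[w[1]]
    j <- keep[w[2]]
    mean_abs <- function(k) {
      others <- setdiff(keep, k)
      mean(abs(corr[k, others]))
    }
    mi <- mean_abs(i)
    mj <- mean_abs(j)
    drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    keep <- setdiff(keep, drop)
  }
  nms[keep]
}
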