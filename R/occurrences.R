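# Species presence records reduced to unique presence cells on the stack grid.

new_occurrence_set <- function(species_id, cells, coords) {
  structure(
    list(
      species_id = species_id,
      cells = cells, coords = coords, n = nrow(cells)
    ),
    class = "occurrence_set"
  )
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat("occurrence_set: species", x$species_id, "-", x$n, "presence cell(s)\n")
  invisible(x)
}

#' Load presence records onto the predictor grid
#'
#' Each point is assigned to the cell containing it (points on a shared cell
#' edge go to the south/east neighbour); duplicate cells collapse to one
#' presence, matching the rasterized-presence convention. Points outside the
#' grid extent or falling on nodata cells are dropped with a message.
#'
#' @param table a data frame with numeric columns `lon` and `lat` (a
#'   `species_id` column, if present, is checked against `species_id`), or a
#'   path to a CSV file with header columns `species_id, lon, lat`.
#' @param stack a `predictor_stack`.
#' @param species_id species identifier; defaults to the single id found in
#'   the table.
#' @return an `occurrence_set`: `species_id`, `cells` (unique (row, col) in
#'   first-seen order), `coords` (cell-center lon/lat), `n`.
#' @export
load_occurrences <- function(table, stack, species_id = NULL) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  if (!all(c("lon", "lat") %in% names(table))) {
    stop("occurrence table needs `lon` and `lat` columns", call. = FALSE)
  }
  if ("species_id" %in% names(table)) {
    ids <- unique(table$species_id)
    if (is.null(species_id)) {
      if (length(ids) != 1L) {
        stop("table holds several species (", paste(ids, collapse = ", "),
          "); pass `species_id`",
          call. = FALSE
        )
      }
      species_id <- ids
    } else {
      table <- table[table$species_id == species_id, , drop = FALSE]
    }
  }
  if (is.null(species_id)) species_id <- "species"
  if (!nrow(table)) stop("no records for species ", species_id, call. = FALSE)

  cells <- points_to_cells(stack, as.numeric(table$lon), as.numeric(table$lat))
  outside <- is.na(cells[, 1])
  n_out <- sum(outside)
  cells <- cells[!outside, , drop = FALSE]
  on_nodata <- !stack$mask[cells]
  n_nodata <- sum(on_nodata)
  cells <- cells[!on_nodata, , drop = FALSE]
  if (n_out + n_nodata > 0) {
    message(
      "load_occurrences: dropped ", n_out, " point(s) outside the grid and ",
      n_nodata, " on nodata cells"
    )
  }
  cells <- unique(cells)
  if (!nrow(cells)) {
    stop("no presence records of '", species_id, "' survive gridding", call. = FALSE)
  }
  new_occurrence_set(species_id, cells, cell_centers(stack, cells))
}

#' Build an occurrence set from a presence raster
#'
#' @param values matrix aligned to `stack`; nonzero, non-`NA` cells are
#'   presences.
#' @param stack a `predictor_stack`.
#' @param species_id species identifier.
#' @return an `occurrence_set`.
#' @export
occurrences_from_grid <- function(values, stack, species_id = "species") {
  if (!identical(dim(values), c(stack$n_rows, stack$n_cols))) {
    stop("presence raster is not aligned with the stack", call. = FALSE)
  }
  cells <- which(!is.na(values) & values != 0, arr.ind = TRUE)
  colnames(cells) <- c("row", "col")
  keep <- stack$mask[cells]
  if (any(!keep)) {
    message("occurrences_from_grid: dropped ", sum(!keep), " presence(s) on nodata cells")
  }
  cells <- cells[keep, , drop = FALSE]
  if (!nrow(cells)) stop("presence raster has no valid presence cells", call. = FALSE)
  new_occurrence_set(species_id, cells, cell_centers(stack, cells))
}
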