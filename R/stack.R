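#' Environmental raster stack
#'
#' An `env_stack` bundles one or more aligned gridded layers for a single
#' scenario/period (e.g. "current" or "SSP585-2090s"). After construction the
#' nodata mask is unified: a cell invalid in any layer is masked in all
#' layers, so every layer shares one valid-cell set.
#'
#' @param spec A [grid_spec()].
#' @param layers Named list of numeric matrices (`n_rows x n_cols`); `NA`
#'   marks nodata.
#' @param scenario_id Scenario/period label.
#' @return An `env_stack` with elements `spec`, `layers`, `mask` (logical
#'   matrix of valid cells) and `scenario_id`.
#' @export
env_stack <- function(spec, layers, scenario_id = "current") {
  stopifnot(inherits(spec, "grid_spec"), length(layers) >= 1)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    abort_sdm("layers must be uniquely named", "sdmflow_layer_error")
  }
  for (l in nm) {
    m <- layers[[l]]
    if (!is.matrix(m) || nrow(m) != spec$n_rows || ncol(m) != spec$n_cols) {
      abort_sdm(sprintf("layer '%s' does not match the grid dimensions", l),
                "sdmflow_alignment_error")
    }
  }
  mask <- Reduce(`&`, lapply(layers, function(m) is.finite(m)))
  layers <- lapply(layers, function(m) { m[!mask] <- NA_real_; m })
  structure(
    list(spec = spec, layers = layers, mask = mask, scenario_id = scenario_id),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf(
    "<env_stack> '%s': %d layer(s) [%s] on %d x %d grid, %d valid cells\n",
    x$scenario_id, length(x$layers),
    paste(names(x$layers), collapse = ", "),
    x$spec$n_rows, x$spec$n_cols, sum(x$mask)
  ))
  invisible(x)
}

#' Layer names of a stack
#' @param stack An [env_stack()].
#' @return Character vector.
#' @export
stack_layers <- function(stack) names(stack$layers)

#' Valid-cell values of a stack as a matrix
#'
#' @param stack An [env_stack()].
#' @param layers Optional subset of layer names.
#' @return Numeric matrix, one row per valid cell (in column-major cell
#'   order), one column per layer. The attribute `"cells"` holds the matrix
#'   cell indices of each row.
#' @export
stack_values <- function(stack, layers = NULL) {
  layers <- layers %||% names(stack$layers)
  missing <- setdiff(layers, names(stack$layers))
  if (length(missing)) {
    abort_sdm(paste0("unknown layer(s): ", paste(missing, collapse = ", ")),
              "sdmflow_lookup_error")
  }
  idx <- which(stack$mask)
  out <- vapply(layers, function(l) stack$layers[[l]][idx], numeric(length(idx)))
  out <- matrix(out, nrow = length(idx), dimnames = list(NULL, layers))
  attr(out, "cells") <- idx
  out
}

#' Read aligned raster layers into a stack
#'
#' Reads a set of ESRI ASCII grids, checks that every grid shares the same
#' geometry (within `tol`), and unifies the nodata mask across layers.
#'
#' @param paths Character vector of `.asc` file paths, or a named vector to
#'   override the default file-stem layer names.
#' @param scenario_id Scenario label stored on the stack.
#' @param tol Absolute tolerance used for the header-alignment check.
#' @return An [env_stack()].
#' @export
read_stack <- function(paths, scenario_id = "current", tol = 1e-9) {
  stopifnot(length(paths) >= 1)
  nm <- names(paths)
  if (is.null(nm)) nm <- rep("", length(paths))
  nm <- ifelse(nm == "", sub("\\.[^.]*$", "", basename(paths)), nm)
  grids <- lapply(paths, read_asc)
  spec <- grids[[1]]$spec
  for (i in seq_along(grids)) {
    if (!grids_aligned(spec, grids[[i]]$spec, tol)) {
      abort_sdm(sprintf("layer '%s' is not aligned with layer '%s'",
                        nm[i], nm[1]),
                "sdmflow_alignment_error")
    }
  }
  layers <- setNames(lapply(grids, `[[`, "values"), nm)
  env_stack(spec, layers, scenario_id)
}

#' Read one ESRI ASCII grid
#'
#' Accepts both `xllcorner`/`yllcorner` and `xllcenter`/`yllcenter` header
#' dialects, normalizing to corner origins internally. Cells equal to the
#' header's `nodata_value` become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return List with elements `spec` ([grid_spec()]) and `values` (matrix,
#'   row 1 = top row as in the file).
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) {
    abort_sdm(paste0("cannot read raster file: ", path), "sdmflow_io_error")
  }
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else {
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort_sdm(paste0("malformed ESRI ASCII header in ", path), "sdmflow_io_error")
  }
  cs <- hdr$cellsize
  x0 <- hdr$xllcorner %||% (hdr$xllcenter - cs / 2)
  y0 <- hdr$yllcorner %||% (hdr$yllcenter - cs / 2)
  if (is.null(x0) || is.null(y0) || is.na(x0) || is.na(y0)) {
    abort_sdm(paste0("missing origin in ESRI ASCII header of ", path),
              "sdmflow_io_error")
  }
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    abort_sdm(sprintf("expected %d values in %s, found %d", nr * nc, path,
                      length(vals)), "sdmflow_io_error")
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(
    spec = grid_spec(nr, nc, x0, y0, cs, crs = "abstract", nodata = nodata),
    values = m
  )
}

#' Write one layer as an ESRI ASCII grid
#'
#' Values are written with 6 significant digits; `NA` cells become the
#' spec's nodata sentinel.
#'
#' @param values Numeric matrix (row 1 = top row).
#' @param spec The [grid_spec()] describing the geometry.
#' @param path Output path.
#' @param digits Significant digits for values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(values, spec, path, digits = 6) {
  stopifnot(is.matrix(values), nrow(values) == spec$n_rows,
            ncol(values) == spec$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$x_origin),
    sprintf("yllcorner %.10g", spec$y_origin),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %g", spec$nodata)
  ), con)
  for (i in seq_len(spec$n_rows)) {
    row <- values[i, ]
    txt <- ifelse(is.na(row), format(spec$nodata),
                  formatC(row, digits = digits, format = "g"))
    writeLines(paste(txt, collapse = " "), con)
  }
  invisible(path)
}

#' Extract predictor values at point locations
#'
#' Points map to cells by the half-open convention
#' `floor((x - x_origin) / cell_size)` (and analogously in y), so a point on
#' a shared edge belongs to the cell to its right/above-origin side.
#'
#' @param stack An [env_stack()].
#' @param points Data frame with `longitude` and `latitude` columns (map x/y
#'   for non-geographic grids).
#' @param layers Optional subset of layers to extract.
#' @return Tibble with one row per input point: the layer values plus
#'   `.row`, `.col`, `.valid` (FALSE for out-of-bounds or masked points).
#' @export
extract_predictors <- function(stack, points, layers = NULL) {
  layers <- layers %||% names(stack$layers)
  cells <- point_to_cell(stack$spec, points$longitude, points$latitude)
  n <- length(cells$row)
  valid <- !cells$out_of_bounds
  masked <- rep(FALSE, n)
  idx <- ifelse(valid, (cells$col - 1L) * stack$spec$n_rows + cells$row, NA_integer_)
  masked[valid] <- !stack$mask[idx[valid]]
  ok <- valid & !masked
  out <- matrix(NA_real_, nrow = n, ncol = length(layers),
                dimnames = list(NULL, layers))
  for (l in layers) out[ok, l] <- stack$layers[[l]][idx[ok]]
  res <- tibble::as_tibble(out)
  res$.row <- cells$row
  res$.col <- cells$col
  res$.valid <- ok
  if (any(!ok)) {
    message(sprintf("extract_predictors: %d point(s) out of bounds or in masked cells",
                    sum(!ok)))
  }
  res
}
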