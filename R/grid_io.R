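# Containers and text I/O for gridded transect sections and habitat maps.
#
# Grid dialect: long-format tab-separated files, one row per grid cell,
# header "distance_m depth_m temperature salinity oxygen chlorophyll" plus
# one column per plankton group.  Cell (0,0) is the top-left cell: surface
# (depth row 0) at the start of the tow (column 0).  Missing cells (below
# the seafloor, sensor gaps) are written as "NA" in every field.

BASE_FIELDS <- c("temperature", "salinity", "oxygen", "chlorophyll")

#' Construct a transect grid
#'
#' A `transect_grid` holds co-registered rasters of the physical fields
#' (temperature in deg C, salinity in psu, oxygen in umol/L), chlorophyll-a
#' (RFU) and any number of per-group plankton density rasters (individuals
#' per microhabitat) on a common distance-by-depth lattice.  Row 1 of every
#' raster is the surface, column 1 the start of the transect; depth grows
#' downward and distance along the tow direction.
#'
#' @param transect_id Character identifier of the section.
#' @param temperature,salinity,oxygen,chlorophyll Numeric matrices of equal
#'   shape `(n_rows, n_cols)`; `NA` marks invalid cells.
#' @param plankton Named list of non-negative density matrices of the same
#'   shape (may be empty).
#' @param cell_length_m Along-track cell length in metres (default 25).
#' @param cell_depth_m Vertical cell extent in metres (default 1).
#' @param valid_mask Logical matrix; `FALSE` marks below-seafloor/missing
#'   cells.  Defaults to cells where all base fields are finite.  Invalid
#'   cells are forced to `NA` in every field.
#' @return An object of class `transect_grid`.
#' @export
transect_grid <- function(transect_id, temperature, salinity, oxygen,
                          chlorophyll, plankton = list(),
                          cell_length_m = 25, cell_depth_m = 1,
                          valid_mask = NULL) {
  stopifnot(is.character(transect_id), length(transect_id) == 1L)
  fields <- list(temperature = temperature, salinity = salinity,
                 oxygen = oxygen, chlorophyll = chlorophyll)
  for (f in names(fields)) {
    if (!is.matrix(fields[[f]]) || !is.numeric(fields[[f]]))
      stop("field '", f, "' must be a numeric matrix")
  }
  dims <- dim(temperature)
  for (f in names(fields)) {
    if (!identical(dim(fields[[f]]), dims))
      stop("all rasters must share shape; '", f, "' differs")
  }
  if (length(plankton)) {
    if (is.null(names(plankton)) || any(names(plankton) == ""))
      stop("plankton rasters must be named")
    for (g in names(plankton)) {
      if (!identical(dim(plankton[[g]]), dims))
        stop("plankton raster '", g, "' has mismatched shape")
      if (any(plankton[[g]] < 0, na.rm = TRUE))
        stop("negative plankton density in group '", g, "'")
    }
  }
  if (any(chlorophyll < 0, na.rm = TRUE))
    stop("negative chlorophyll values")
  if (is.null(valid_mask)) {
    valid_mask <- Reduce(`&`, lapply(fields, is.finite))
  }
  stopifnot(identical(dim(valid_mask), dims), is.logical(valid_mask))
  # invalid cells carry the NA sentinel in every field
  for (f in names(fields)) fields[[f]][!valid_mask] <- NA_real_
  plankton <- lapply(plankton, function(m) { m[!valid_mask] <- NA_real_; m })
  structure(list(transect_id = transect_id,
                 cell_length_m = cell_length_m,
                 cell_depth_m = cell_depth_m,
                 n_rows = dims[1L], n_cols = dims[2L],
                 temperature = fields$temperature,
                 salinity = fields$salinity,
                 oxygen = fields$oxygen,
                 chlorophyll = fields$chlorophyll,
                 plankton = plankton,
                 valid_mask = valid_mask),
            class = "transect_grid")
}

#' @export
print.transect_grid <- function(x, ...) {
  cat("<transect_grid> ", x$transect_id, ": ",
      x$n_rows, " depth rows x ", x$n_cols, " columns (",
      x$cell_depth_m, " m x ", x$cell_length_m, " m cells), ",
      sum(x$valid_mask), " valid cells, plankton groups: ",
      if (length(x$plankton)) paste(names(x$plankton), collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Construct a habitat map
#'
#' Integer macro-habitat label per grid cell; `-1` marks transition/noise
#' cells, `NA` marks invalid (below-seafloor) cells.
#'
#' @param transect_id Character identifier.
#' @param labels Integer matrix with values `>= -1` or `NA`.
#' @param cell_length_m,cell_depth_m Cell dimensions in metres.
#' @return An object of class `habitat_map`.
#' @export
habitat_map <- function(transect_id, labels, cell_length_m = 25,
                        cell_depth_m = 1) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (any(labels < -1L, na.rm = TRUE))
    stop("habitat labels below -1 are not allowed")
  structure(list(transect_id = transect_id, labels = labels,
                 cell_length_m = cell_length_m, cell_depth_m = cell_depth_m),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  k <- sort(unique(x$labels[x$labels >= 0L]))
  cat("<habitat_map> ", x$transect_id, ": ", nrow(x$labels), " x ",
      ncol(x$labels), " cells, ", length(k), " macro-habitats, ",
      sum(x$labels == -1L, na.rm = TRUE), " transition cells\n", sep = "")
  invisible(x)
}

# numbers are printed with 17 significant digits so finite doubles
# round-trip bit-exactly through the text format
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- "NA"
  out
}

.grid_coords <- function(n_rows, n_cols, cell_length_m, cell_depth_m) {
  list(distance_m = rep((seq_len(n_cols) - 1) * cell_length_m,
                        each = n_rows),
       depth_m = rep((seq_len(n_rows) - 1) * cell_depth_m,
                     times = n_cols))
}

#' Write a transect grid to a tab-separated file
#'
#' @param grid A [transect_grid()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_transect_grid <- function(grid, path) {
  stopifnot(inherits(grid, "transect_grid"))
  co <- .grid_coords(grid$n_rows, grid$n_cols,
                     grid$cell_length_m, grid$cell_depth_m)
  cols <- c(list(distance_m = .fmt_num(co$distance_m),
                 depth_m = .fmt_num(co$depth_m)),
            lapply(grid[BASE_FIELDS], function(m) .fmt_num(as.vector(m))),
            lapply(grid$plankton, function(m) .fmt_num(as.vector(m))))
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# parse the coordinate axis of a long-format file: values must form a
# uniformly spaced lattice, else the file is structurally invalid
.axis_from <- function(values, what) {
  u <- sort(unique(values))
  if (length(u) == 1L) return(list(levels = u, step = 1))
  steps <- diff(u)
  if (max(abs(steps - steps[1L])) > 1e-6 * max(abs(steps)))
    stop("non-rectangular lattice: uneven ", what, " spacing")
  list(levels = u, step = steps[1L])
}

#' Read a transect grid from a tab-separated file
#'
#' Expects the long-format dialect written by [write_transect_grid()]:
#' columns `distance_m`, `depth_m`, the four base fields, then one column
#' per plankton group; one row per grid cell; missing values as `NA`.
#' Cell sizes are inferred from the coordinate spacing.
#'
#' @param path Input file path.
#' @param transect_id Identifier to attach; defaults to the file name.
#' @return A [transect_grid()].
#' @export
read_transect_grid <- function(path, transect_id = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, na.strings = "NA",
                          fileEncoding = "UTF-8")
  need <- c("distance_m", "depth_m", BASE_FIELDS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  groups <- setdiff(names(df), need)
  dax <- .axis_from(df$distance_m, "distance")
  zax <- .axis_from(df$depth_m, "depth")
  n_cols <- length(dax$levels); n_rows <- length(zax$levels)
  if (nrow(df) != n_rows * n_cols)
    stop("non-rectangular lattice: ", nrow(df), " rows for a ",
         n_rows, " x ", n_cols, " grid")
  ri <- match(df$depth_m, zax$levels)
  ci <- match(df$distance_m, dax$levels)
  idx <- ri + (ci - 1L) * n_rows
  if (anyDuplicated(idx))
    stop("non-rectangular lattice: duplicated cell coordinates")
  put <- function(v) {
    m <- matrix(NA_real_, n_rows, n_cols)
    m[idx] <- v
    m
  }
  for (g in groups) if (any(df[[g]] < 0, na.rm = TRUE))
    stop("negative density in plankton column '", g, "'")
  if (any(df$chlorophyll < 0, na.rm = TRUE))
    stop("negative chlorophyll values in file")
  transect_grid(
    transect_id = if (is.null(transect_id))
      sub("\\.[^.]*$", "", basename(path)) else transect_id,
    temperature = put(df$temperature), salinity = put(df$salinity),
    oxygen = put(df$oxygen), chlorophyll = put(df$chlorophyll),
    plankton = stats::setNames(lapply(groups, function(g) put(df[[g]])),
                               groups),
    cell_length_m = dax$step, cell_depth_m = zax$step)
}

#' Write a habitat map to a tab-separated file
#'
#' Columns `distance_m`, `depth_m`, `label`; invalid cells have label `NA`.
#'
#' @param map A [habitat_map()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_habitat_map <- function(map, path) {
  stopifnot(inherits(map, "habitat_map"))
  co <- .grid_coords(nrow(map$labels), ncol(map$labels),
                     map$cell_length_m, map$cell_depth_m)
  lab <- as.vector(map$labels)
  df <- data.frame(distance_m = .fmt_num(co$distance_m),
                   depth_m = .fmt_num(co$depth_m),
                   label = ifelse(is.na(lab), "NA", as.character(lab)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a habitat map from a tab-separated file
#'
#' @param path Input file path.
#' @param transect_id Identifier to attach; defaults to the file name.
#' @return A [habitat_map()].
#' @export
read_habitat_map <- function(path, transect_id = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = "NA", fileEncoding = "UTF-8")
  need <- c("distance_m", "depth_m", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  dax <- .axis_from(df$distance_m, "distance")
  zax <- .axis_from(df$depth_m, "depth")
  n_cols <- length(dax$levels); n_rows <- length(zax$levels)
  if (nrow(df) != n_rows * n_cols)
    stop("non-rectangular lattice in habitat map file")
  if (any(df$label < -1L, na.rm = TRUE))
    stop("habitat labels below -1 are not allowed")
  idx <- match(df$depth_m, zax$levels) +
    (match(df$distance_m, dax$levels) - 1L) * n_rows
  if (anyDuplicated(idx))
    stop("non-rectangular lattice: duplicated cell coordinates")
  m <- matrix(NA_integer_, n_rows, n_cols)
  m[idx] <- as.integer(df$label)
  habitat_map(if (is.null(transect_id)) sub("\\.[^.]*$", "", basename(path))
              else transect_id,
              m, cell_length_m = dax$step, cell_depth_m = zax$step)
}
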