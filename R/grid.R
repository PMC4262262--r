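#' Create an empty landscape grid
#'
#' The landscape is a regular raster of square cells (default edge 10 m, so
#' 100 m2 per cell) indexed row-major from the upper left. State is held in
#' columnar form: per-cell matrices for herb covers and seed banks, one
#' data.frame of woody agents, and per-cell management and vegetation-type
#' vectors.
#'
#' @param n_cols,n_rows grid dimensions.
#' @param cellsize cell edge length in m; cell area is `cellsize^2`.
#' @param woody woody species parameter table ([woody_species_defaults()]).
#' @param herbsp herb species parameter table ([herb_species_defaults()]).
#' @param mown,grazed logical vectors (recycled) marking managed cells.
#' @param I_C,I_G,I_T cutting/grazing/trampling intensities in \[0, 100\]
#'   (recycled); defaults follow the mown/grazed flags.
#' @return A list of class `woods_grid`.
#' @export
woods_grid <- function(n_cols, n_rows, cellsize = 10,
                       woody = woody_species_defaults(),
                       herbsp = herb_species_defaults(),
                       mown = FALSE, grazed = FALSE,
                       I_C = NULL, I_G = NULL, I_T = NULL) {
  stopifnot(n_cols >= 1, n_rows >= 1, cellsize > 0)
  n <- as.integer(n_cols) * as.integer(n_rows)
  mown <- rep_len(as.logical(mown), n)
  grazed <- rep_len(as.logical(grazed), n)
  if (is.null(I_C)) I_C <- ifelse(mown, 100, 0)
  if (is.null(I_G)) I_G <- ifelse(grazed, 100, 0)
  if (is.null(I_T)) I_T <- ifelse(grazed, 50, 0)
  g <- structure(list(
    n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
    cellsize = cellsize, A = cellsize^2, n_cells = n,
    woody = woody, herbsp = herbsp,
    herb = matrix(0, n, nrow(herbsp), dimnames = list(NULL, herbsp$name)),
    bank = matrix(0, n, nrow(woody), dimnames = list(NULL, woody$name)),
    surplus = matrix(0, n, nrow(woody), dimnames = list(NULL, woody$name)),
    agents = empty_agents(),
    mown = mown, grazed = grazed,
    I_C = rep_len(I_C, n), I_G = rep_len(I_G, n), I_T = rep_len(I_T, n),
    veg = rep("fallow_grassland", n),
    year = 0L
  ), class = "woods_grid")
  g$veg <- classify_vegetation(g)
  g
}

empty_agents <- function() {
  data.frame(cell = integer(), sp = integer(), H = numeric(),
             age = numeric(), age_max = numeric(), D = numeric(),
             C = numeric(), browsed = logical())
}

#' @export
print.woods_grid <- function(x, ...) {
  cat(sprintf("woods_grid: %d x %d cells of %.0f m2 (%.2f ha), year %d\n",
              x$n_cols, x$n_rows, x$A,
              x$n_cells * x$A / 1e4, x$year))
  cat(sprintf("  agents: %d (%s)\n", nrow(x$agents),
              if (nrow(x$agents)) paste(sprintf(
                "%s: %d", x$woody$name[sort(unique(x$agents$sp))],
                tabulate(x$agents$sp, nrow(x$woody))[sort(unique(x$agents$sp))]),
                collapse = ", ") else "none"))
  cat("  vegetation: ",
      paste(sprintf("%s %d", names(table(x$veg)), table(x$veg)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

## ---- cell indexing -------------------------------------------------------

#' Cell index from column/row (row-major, origin upper left)
#' @param grid a `woods_grid`.
#' @param col,row 1-based column and row indices.
#' @return Integer cell index.
#' @export
cell_index <- function(grid, col, row) {
  stopifnot(all(col >= 1 & col <= grid$n_cols),
            all(row >= 1 & row <= grid$n_rows))
  (as.integer(row) - 1L) * grid$n_cols + as.integer(col)
}

#' Column/row of a cell index
#' @param grid a `woods_grid`.
#' @param cell integer cell index.
#' @return data.frame with columns `col`, `row`.
#' @export
cell_colrow <- function(grid, cell) {
  cell <- as.integer(cell)
  data.frame(col = (cell - 1L) %% grid$n_cols + 1L,
             row = (cell - 1L) %/% grid$n_cols + 1L)
}

#' Centroid-to-centroid distance between two cells
#'
#' Euclidean distance between cell centroids:
#' `cellsize * sqrt((col1-col2)^2 + (row1-row2)^2)`.
#' @param col1,row1,col2,row2 cell indices (vectorized).
#' @param cellsize cell edge length (m).
#' @return Distance in m.
#' @export
centroid_distance <- function(col1, row1, col2, row2, cellsize = 10) {
  cellsize * sqrt((col1 - col2)^2 + (row1 - row2)^2)
}

## ---- cover aggregates ----------------------------------------------------

#' Per-cell cover sums of the woody guilds
#'
#' @param grid a `woods_grid`.
#' @return A list with per-cell numeric vectors: `tree` (crown cover of all
#'   tree agents), `broom` (crown cover of broom agents), `thorny`
#'   (bramble + blackthorn herb-layer cover).
#' @export
cover_summary <- function(grid) {
  n <- grid$n_cells
  tree <- numeric(n); broom <- numeric(n)
  if (nrow(grid$agents)) {
    is_b <- grid$woody$is_broom[grid$agents$sp]
    if (any(!is_b)) {
      t <- rowsum(grid$agents$C[!is_b], grid$agents$cell[!is_b])
      tree[as.integer(rownames(t))] <- t
    }
    if (any(is_b)) {
      b <- rowsum(grid$agents$C[is_b], grid$agents$cell[is_b])
      broom[as.integer(rownames(b))] <- b
    }
  }
  thorny <- if (any(grid$herbsp$is_thorny_shrub))
    rowSums(grid$herb[, grid$herbsp$is_thorny_shrub, drop = FALSE])
  else numeric(n)
  list(tree = tree, broom = broom, thorny = thorny)
}

#' Classify the vegetation type of every cell
#'
#' Categories, in order of precedence:
#' \itemize{
#'   \item `forest`: tree crown cover at least 50\% of the cell;
#'   \item `shrub`: bush cover (broom agents + bramble + blackthorn) at
#'     least 10\% of the cell;
#'   \item `grassland`: mown or grazed;
#'   \item `disturbed_ground`: unmanaged with a nearly bare herb layer
#'     (total herb cover below `bare_frac` of the cell);
#'   \item `fallow_grassland`: everything else.
#' }
#' @param grid a `woods_grid`.
#' @param bare_frac herb-cover fraction below which an unmanaged cell counts
#'   as disturbed ground.
#' @return Character vector of length `n_cells`.
#' @export
classify_vegetation <- function(grid, bare_frac = 0.05) {
  cov <- cover_summary(grid)
  herb_tot <- rowSums(grid$herb)
  out <- rep("fallow_grassland", grid$n_cells)
  out[!grid$mown & !grid$grazed & herb_tot < bare_frac * grid$A] <-
    "disturbed_ground"
  out[grid$mown | grid$grazed] <- "grassland"
  shrubby <- cov$broom + cov$thorny >= 0.10 * grid$A
  out[shrubby] <- "shrub"
  out[cov$tree >= 0.50 * grid$A] <- "forest"
  out
}

## ---- Esri ASCII raster I/O ----------------------------------------------

#' Read an Esri ASCII grid
#'
#' Parses the six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by `nrows` rows of values, top row
#' first. NODATA values become `NA`.
#'
#' @param path file path.
#' @return A list with `values` (numeric matrix, `nrows` x `ncols`, row 1 =
#'   top), `cellsize`, `xllcorner`, `yllcorner`, `nodata`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "NODATA_value")
  hdr <- list()
  for (i in seq_along(keys)) {
    if (i > length(lines))
      stop(sprintf("malformed Esri ASCII header at line %d: expected '%s'",
                   i, keys[i]))
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2 || tolower(parts[1]) != tolower(keys[i]) ||
        is.na(suppressWarnings(as.numeric(parts[2]))))
      stop(sprintf("malformed Esri ASCII header at line %d: expected '%s'",
                   i, keys[i]))
    hdr[[keys[i]]] <- as.numeric(parts[2])
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- lines[-seq_len(6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nr)
    stop(sprintf("Esri ASCII body has %d rows, header says %d",
                 length(body), nr))
  vals <- lapply(body[seq_len(nr)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(vals) != nc))
    stop(sprintf("Esri ASCII row with %d values, header says %d columns",
                 lengths(vals)[which(lengths(vals) != nc)[1]], nc))
  m <- do.call(rbind, vals)
  m[m == hdr$NODATA_value] <- NA
  list(values = m, cellsize = hdr$cellsize, xllcorner = hdr$xllcorner,
       yllcorner = hdr$yllcorner, nodata = hdr$NODATA_value)
}

#' Write an Esri ASCII grid
#'
#' Inverse of [read_esri_ascii()]: finite values round-trip exactly
#' (written with full precision), `NA` becomes the NODATA value.
#' @param values numeric matrix, row 1 = top row.
#' @param path output file path.
#' @param cellsize,xllcorner,yllcorner grid geometry.
#' @param nodata NODATA marker value.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(values, path, cellsize = 10,
                             xllcorner = 0, yllcorner = 0, nodata = -9999) {
  values <- as.matrix(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(values)),
    sprintf("nrows %d", nrow(values)),
    sprintf("xllcorner %.10g", xllcorner),
    sprintf("yllcorner %.10g", yllcorner),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  v <- values
  v[is.na(v)] <- nodata
  writeLines(apply(v, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

#' Per-cell values as a raster matrix
#'
#' Reshapes a per-cell vector (row-major, upper-left origin) into the
#' `n_rows` x `n_cols` matrix layout used by the raster I/O.
#' @param grid a `woods_grid`.
#' @param x per-cell vector of length `n_cells`.
#' @return Numeric matrix.
#' @export
as_raster <- function(grid, x) {
  stopifnot(length(x) == grid$n_cells)
  matrix(x, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}
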