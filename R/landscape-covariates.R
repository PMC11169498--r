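# Landscape covariates from categorical grids: class proportions in circular
# buffers, burned-area fraction, local fire status, a Pearson correlation
# screen, and covariate standardization with exact back-transforms.

#' Categorical land-cover grid
#'
#' A rectangular matrix of non-negative integer class codes with a cell size
#' and a lower-left origin in planar metres. Row 1 of `codes` is the top
#' (northernmost) row, as in ASCII grid files.
#'
#' @param codes integer matrix of class codes.
#' @param cell_size_m cell edge length in metres.
#' @param origin numeric `(x0, y0)` of the lower-left grid corner.
#' @return an object of class `land_grid`.
#' @export
land_grid <- function(codes, cell_size_m, origin = c(0, 0)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (any(codes < 0)) stop("class codes must be non-negative integers")
  stopifnot(cell_size_m > 0, length(origin) == 2)
  structure(list(codes = codes, cell_size_m = cell_size_m,
                 origin = as.numeric(origin)),
            class = "land_grid")
}

# Coordinates of all cell centers; row 1 of the matrix is the top row.
grid_cell_centers <- function(grid) {
  nr <- nrow(grid$codes); nc <- ncol(grid$codes)
  cs <- grid$cell_size_m
  x <- grid$origin[1] + (seq_len(nc) - 0.5) * cs
  y <- grid$origin[2] + (nr - seq_len(nr) + 0.5) * cs
  list(x = x, y = y)
}

# Indices and codes of cells whose centers lie within radius_m of center.
cells_in_buffer <- function(grid, center, radius_m) {
  cc <- grid_cell_centers(grid)
  dx2 <- (cc$x - center[1])^2
  dy2 <- (cc$y - center[2])^2
  inside <- outer(dy2, dx2, `+`) <= radius_m^2
  grid$codes[inside]
}

#' Proportion of land-cover classes inside a circular buffer
#'
#' The fraction of grid cells inside the buffer (cell-center-within-radius
#' rule) whose code belongs to `codes`.
#'
#' @param grid a [land_grid()].
#' @param center numeric `(x, y)` buffer center in metres.
#' @param radius_m buffer radius (default 1000 m).
#' @param codes integer set of class codes counted as the target class.
#' @return proportion in `[0, 1]`.
#' @export
buffer_proportion <- function(grid, center, radius_m = 1000, codes) {
  stopifnot(inherits(grid, "land_grid"), radius_m > 0, length(center) == 2)
  vals <- cells_in_buffer(grid, center, radius_m)
  if (!length(vals)) stop("buffer contains no grid cell centers (off-grid?)")
  mean(vals %in% codes)
}

#' Burned-area fraction in a circular buffer
#'
#' [buffer_proportion()] on a binary burn grid with target code 1.
#'
#' @inheritParams buffer_proportion
#' @export
burned_fraction_at_station <- function(grid, center, radius_m = 1000) {
  buffer_proportion(grid, center, radius_m, codes = 1L)
}

#' Local fire status of a station
#'
#' A station is `"burned"` if any burned cell center of the binary burn grid
#' falls within `radius_m` (default 30 m, the field rule used to classify
#' stations), else `"unburned"`. When the buffer is smaller than the grid
#' resolution and contains no cell center, the status of the cell containing
#' the station is used; a station outside the grid is an error.
#'
#' @inheritParams buffer_proportion
#' @export
local_fire_status <- function(grid, center, radius_m = 30) {
  stopifnot(inherits(grid, "land_grid"))
  vals <- cells_in_buffer(grid, center, radius_m)
  if (!length(vals)) {
    nr <- nrow(grid$codes); nc <- ncol(grid$codes); cs <- grid$cell_size_m
    col <- floor((center[1] - grid$origin[1]) / cs) + 1
    row <- nr - floor((center[2] - grid$origin[2]) / cs)
    if (col < 1 || col > nc || row < 1 || row > nr) {
      stop("buffer contains no grid cell centers (off-grid?)")
    }
    vals <- grid$codes[row, col]
  }
  if (any(vals == 1L)) "burned" else "unburned"
}

#' Pearson correlation screen among candidate covariates
#'
#' Computes all pairwise Pearson correlations and flags pairs exceeding the
#' threshold. The default mirrors a screen on positive correlation
#' (signed correlation greater than the threshold); `use_abs = TRUE` flags
#' on the absolute value. The default
#' removal policy drops both members of every flagged pair;
#' `policy = "keep-one"` retains the first member. Zero-variance columns
#' yield `NA` correlations, which are reported but never flagged.
#'
#' @param table data frame of numeric candidate columns.
#' @param threshold correlation threshold (default 0.5).
#' @param use_abs flag on absolute correlation.
#' @param policy `"drop-both"` (default) or `"keep-one"`.
#' @return list with `correlations` (matrix), `flagged`
#'   (`data.frame(var1, var2, r)`), `retained` (column names kept) and
#'   `dropped`.
#' @export
correlation_screen <- function(table, threshold = 0.5, use_abs = FALSE,
                               policy = c("drop-both", "keep-one")) {
  policy <- match.arg(policy)
  num <- table[vapply(table, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("need at least 3 rows for a correlation screen")
  if (ncol(num) < 2) stop("need at least 2 numeric columns")
  zero_var <- vapply(num, function(x) sd(x) == 0, logical(1))
  cors <- suppressWarnings(cor(num))
  flagged <- data.frame(var1 = character(), var2 = character(), r = numeric())
  cols <- names(num)
  for (i in seq_along(cols)) {
    for (j in seq_along(cols)) {
      if (j <= i || zero_var[i] || zero_var[j]) next
      r <- cors[i, j]
      stat <- if (use_abs) abs(r) else r
      if (!is.na(stat) && stat > threshold) {
        flagged <- rbind(flagged, data.frame(var1 = cols[i], var2 = cols[j], r = r))
      }
    }
  }
  dropped <- if (nrow(flagged) == 0) character(0) else
    if (policy == "drop-both") unique(c(flagged$var1, flagged$var2)) else
      unique(flagged$var2)
  list(correlations = cors, flagged = flagged,
       retained = setdiff(cols, dropped), dropped = dropped)
}

#' Standardize covariate columns with recoverable scaling
#'
#' Replaces the named columns with z-scores and stores the means and sds as
#' attributes so [destandardize()] recovers the originals exactly.
#'
#' @param table data frame.
#' @param columns character vector of numeric column names.
#' @return the table with scaled columns and attributes `scaled_center`,
#'   `scaled_scale`.
#' @export
standardize <- function(table, columns) {
  means <- sds <- setNames(numeric(length(columns)), columns)
  for (col in columns) {
    x <- table[[col]]
    if (is.null(x)) stop("no such column: ", col)
    s <- sd(x)
    if (s == 0) stop("zero standard deviation in column: ", col)
    means[col] <- mean(x); sds[col] <- s
    table[[col]] <- (x - means[col]) / s
  }
  attr(table, "scaled_center") <- means
  attr(table, "scaled_scale") <- sds
  table
}

#' @rdname standardize
#' @export
destandardize <- function(table) {
  means <- attr(table, "scaled_center")
  sds <- attr(table, "scaled_scale")
  if (is.null(means)) stop("table was not produced by standardize()")
  for (col in names(means)) {
    table[[col]] <- table[[col]] * sds[col] + means[col]
  }
  attr(table, "scaled_center") <- NULL
  attr(table, "scaled_scale") <- NULL
  table
}

#' Read / write a plain-text ASCII grid
#'
#' The format is the ESRI ASCII raster header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value`) followed
#' by the code matrix, top row first.
#'
#' @param path file path.
#' @return a [land_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr))) {
    stop("ASCII grid header incomplete; need ", paste(req, collapse = ", "))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("grid body does not match header dimensions")
  }
  codes <- matrix(as.integer(vals), nrow = hdr$nrows, ncol = hdr$ncols,
                  byrow = TRUE)
  land_grid(codes, hdr$cellsize, c(hdr$xllcorner, hdr$yllcorner))
}

#' @rdname read_ascii_grid
#' @param grid a [land_grid()] to write.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "land_grid"))
  hdr <- c(sprintf("ncols %d", ncol(grid$codes)),
           sprintf("nrows %d", nrow(grid$codes)),
           sprintf("xllcorner %g", grid$origin[1]),
           sprintf("yllcorner %g", grid$origin[2]),
           sprintf("cellsize %g", grid$cell_size_m))
  body <- apply(grid$codes, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Assemble the site covariate table from grids and station locations
#'
#' For each station: local fire status (30-m rule), burned-area fraction and
#' land-class proportions in 1-km buffers, carried camera counts, plus
#' standardized copies of the continuous covariates.
#'
#' @param landcover a [land_grid()] of land-cover codes.
#' @param burn a binary [land_grid()] (1 = burned).
#' @param stations `data.frame` with `station_id`, `x`, `y`, `n_cameras`,
#'   `forest_type`.
#' @param class_map named list mapping class labels to integer code sets,
#'   e.g. `list(forest = c(3, 4), grassland = 12, water = c(11, 33))`.
#' @param buffer_m class/burn buffer radius (default 1000).
#' @param fire_buffer_m local fire status radius (default 30).
#' @return covariate `data.frame` with one row per station.
#' @export
extract_site_covariates <- function(landcover, burn, stations, class_map,
                                    buffer_m = 1000, fire_buffer_m = 30) {
  stopifnot(all(c("station_id", "x", "y", "n_cameras", "forest_type") %in%
                  names(stations)))
  out <- stations[, c("station_id", "x", "y", "n_cameras", "forest_type")]
  for (lbl in names(class_map)) {
    out[[lbl]] <- vapply(seq_len(nrow(stations)), function(i) {
      buffer_proportion(landcover, c(stations$x[i], stations$y[i]),
                        buffer_m, class_map[[lbl]])
    }, numeric(1))
  }
  out$burned_area <- vapply(seq_len(nrow(stations)), function(i) {
    burned_fraction_at_station(burn, c(stations$x[i], stations$y[i]), buffer_m)
  }, numeric(1))
  out$local_fire <- vapply(seq_len(nrow(stations)), function(i) {
    local_fire_status(burn, c(stations$x[i], stations$y[i]), fire_buffer_m)
  }, character(1))
  add_standardized(out, c(intersect("grassland", names(out)),
                          "burned_area", "n_cameras"))
}
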