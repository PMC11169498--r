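# Detection-history construction: station merging by spatial proximity,
# occasion calendars, species x site detection matrices, data augmentation,
# and plain-text I/O for the resulting objects.

#' Detection data container
#'
#' Bundles the species x sites detection-frequency matrix `Y` (occasions
#' with at least one record), the per-site occasion counts `V`, and the
#' augmentation mask.
#'
#' @param Y integer matrix, species in rows, sites in columns.
#' @param V integer vector of occasions per site.
#' @param augmented logical per species; augmented rows must be all zero.
#' @return an object of class `detection_data`.
#' @export
detection_data <- function(Y, V, augmented = rep(FALSE, nrow(Y))) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "integer"
  V <- as.integer(V)
  stopifnot(length(V) == ncol(Y), all(V >= 0), length(augmented) == nrow(Y))
  if (any(Y < 0) || any(sweep(Y, 2, V) > 0)) {
    stop("Y must satisfy 0 <= Y[i, j] <= V[j]")
  }
  if (any(augmented & rowSums(Y) > 0)) {
    stop("augmented species rows must be all zero")
  }
  if (!is.null(colnames(Y))) names(V) <- colnames(Y)
  structure(list(Y = Y, V = V,
                 species = rownames(Y), sites = colnames(Y),
                 augmented = augmented),
            class = "detection_data")
}

#' @export
print.detection_data <- function(x, ...) {
  cat(sprintf("detection_data: %d species (%d augmented) x %d sites, V in [%d, %d]\n",
              nrow(x$Y), sum(x$augmented), ncol(x$Y), min(x$V), max(x$V)))
  invisible(x)
}

#' Merge camera stations closer than an independence threshold
#'
#' Stations closer than `threshold_m` (Euclidean, planar metres) are grouped
#' by connected components of the proximity graph; each group becomes one
#' station at the member centroid whose camera count is the group sum and
#' whose active window is the union of member windows. Records from merged
#' members are pooled downstream via the returned id mapping.
#'
#' Coordinates must already be in a projected CRS in metres: longitude and
#' latitude magnitudes (|x| <= 360 and |y| <= 90) are refused rather than
#' silently treated as metres.
#'
#' @param deployments `data.frame` with `station_id`, `x`, `y`,
#'   `start_date`, `end_date`, `n_cameras`.
#' @param threshold_m merge distance in metres (default 500).
#' @return list with `deployments` (merged table) and `mapping`
#'   (`data.frame` old -> new id).
#' @export
merge_stations <- function(deployments, threshold_m = 500) {
  req <- c("station_id", "x", "y", "start_date", "end_date", "n_cameras")
  if (!all(req %in% names(deployments))) {
    stop("deployments must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(deployments$station_id)) {
    stop("duplicate station ids in deployments")
  }
  if (all(abs(deployments$x) <= 360) && all(abs(deployments$y) <= 90)) {
    stop("coordinates look geographic (lon/lat); project to planar metres first")
  }
  n <- nrow(deployments)
  d <- as.matrix(dist(deployments[, c("x", "y")]))
  # union-find over the < threshold graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && d[i, j] < threshold_m) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  merged <- do.call(rbind, lapply(groups, function(idx) {
    m <- deployments[idx, , drop = FALSE]
    data.frame(
      station_id = paste(sort(m$station_id), collapse = "+"),
      x = mean(m$x), y = mean(m$y),
      start_date = min(as.Date(m$start_date)),
      end_date = max(as.Date(m$end_date)),
      n_cameras = sum(m$n_cameras), stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  merged <- merged[order(merged$station_id), , drop = FALSE]
  mapping <- do.call(rbind, lapply(groups, function(idx) {
    data.frame(old_id = deployments$station_id[idx],
               new_id = paste(sort(deployments$station_id[idx]), collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  rownames(mapping) <- NULL
  list(deployments = merged, mapping = mapping[order(mapping$old_id), ])
}

#' Build occasion calendars and visit counts
#'
#' Splits each station's active window into consecutive non-overlapping
#' occasions of `occasion_days` days from the start date. A trailing partial
#' window counts as one occasion by default (`V = ceiling(days /
#' occasion_days)`); set `drop_partial = TRUE` to truncate instead.
#'
#' @param deployments deployment table (see [merge_stations()]).
#' @param occasion_days window length in days (default 5).
#' @param drop_partial drop a trailing window shorter than `occasion_days`.
#' @return list with `calendars` (named list of `data.frame(occasion,
#'   start, end)` per station) and `V` (named integer vector).
#' @export
build_occasions <- function(deployments, occasion_days = 5L,
                            drop_partial = FALSE) {
  stopifnot(occasion_days >= 1)
  start <- as.Date(deployments$start_date)
  end <- as.Date(deployments$end_date)
  if (any(end < start)) stop("end_date before start_date")
  days <- as.integer(end - start) + 1L
  if (any(days > 10000L)) stop("active window exceeds 10,000 days")
  V <- if (drop_partial) days %/% occasion_days else
    as.integer(ceiling(days / occasion_days))
  if (any(V < 1L)) stop("a station has no complete occasion; lower occasion_days")
  calendars <- lapply(seq_len(nrow(deployments)), function(i) {
    k <- seq_len(V[i])
    data.frame(occasion = k,
               start = start[i] + (k - 1L) * occasion_days,
               end = pmin(start[i] + k * occasion_days - 1L, end[i]))
  })
  names(calendars) <- deployments$station_id
  names(V) <- deployments$station_id
  list(calendars = calendars, V = V)
}

#' Build the species x site detection matrix from records
#'
#' `Y[i, j]` counts the occasions at station `j` containing at least one
#' record of species `i`; multiple records within an occasion collapse to
#' one. Records falling outside every occasion window of their station are
#' dropped with a warning (the drop count is attached as attribute
#' `n_dropped`).
#'
#' @param records `data.frame` with `station_id`, `species`, `timestamp`.
#' @param calendars occasion calendars from [build_occasions()].
#' @param V occasion counts from [build_occasions()].
#' @param species optional character vector fixing the row set and order
#'   (species never recorded then get all-zero rows).
#' @return a [detection_data()] object.
#' @export
build_detection_matrix <- function(records, calendars, V, species = NULL) {
  stations <- names(calendars)
  if (nrow(records) && !all(records$station_id %in% stations)) {
    stop("records reference unknown station(s): ",
         paste(setdiff(unique(records$station_id), stations), collapse = ", "))
  }
  if (is.null(species)) species <- sort(unique(records$species))
  Y <- matrix(0L, length(species), length(stations),
              dimnames = list(species, stations))
  dropped <- 0L
  if (nrow(records)) {
    rec_date <- as.Date(as.POSIXct(records$timestamp, tz = "UTC"), tz = "UTC")
    for (st in unique(records$station_id)) {
      idx <- which(records$station_id == st)
      cal <- calendars[[st]]
      o <- findInterval(as.numeric(rec_date[idx]), as.numeric(cal$start))
      ok <- o >= 1L & rec_date[idx] <= cal$end[pmax(o, 1L)]
      dropped <- dropped + sum(!ok)
      if (!any(ok)) next
      hits <- unique(data.frame(species = records$species[idx][ok],
                                occasion = o[ok], stringsAsFactors = FALSE))
      hits <- hits[hits$species %in% species, , drop = FALSE]
      if (nrow(hits)) {
        tab <- table(hits$species)
        Y[names(tab), st] <- Y[names(tab), st] + as.integer(tab)
      }
    }
  }
  if (dropped > 0L) {
    warning(dropped, " record(s) fell outside every occasion window and were dropped")
  }
  out <- detection_data(Y, V[stations])
  attr(out, "n_dropped") <- dropped
  out
}

#' Append augmented all-zero detection histories
#'
#' Data augmentation for community-size estimation: `n_dummy` species with
#' all-zero histories join the matrix flagged `augmented = TRUE`, so the
#' model can estimate how many undetected species the community plausibly
#' holds.
#'
#' @param data a [detection_data()] object.
#' @param n_dummy number of augmented species (default 8).
#' @param labels optional names for the augmented rows.
#' @return a [detection_data()] object with `nrow(Y) + n_dummy` rows.
#' @export
augment_detections <- function(data, n_dummy = 8L, labels = NULL) {
  stopifnot(inherits(data, "detection_data"), n_dummy >= 0)
  if (n_dummy == 0L) return(data)
  if (is.null(labels)) labels <- sprintf("aug%02d", seq_len(n_dummy))
  stopifnot(length(labels) == n_dummy)
  zero <- matrix(0L, n_dummy, ncol(data$Y),
                 dimnames = list(labels, colnames(data$Y)))
  detection_data(rbind(data$Y, zero), data$V,
                 augmented = c(data$augmented, rep(TRUE, n_dummy)))
}

#' Read camera-trap records / station deployments from CSV
#'
#' Records need columns `station_id`, `species`, `timestamp` (ISO-8601);
#' deployments need `station_id`, `x`, `y`, `start_date`, `end_date`,
#' `n_cameras`.
#'
#' @param path CSV file path.
#' @return a `data.frame` with parsed date/time columns.
#' @export
read_camera_records <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("station_id", "species", "timestamp")
  if (!all(req %in% names(rec))) {
    stop("record table must have columns: ", paste(req, collapse = ", "))
  }
  rec$timestamp <- as.POSIXct(rec$timestamp, tz = "UTC")
  rec
}

#' @rdname read_camera_records
#' @export
read_deployments <- function(path) {
  dep <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("station_id", "x", "y", "start_date", "end_date", "n_cameras")
  if (!all(req %in% names(dep))) {
    stop("deployment table must have columns: ", paste(req, collapse = ", "))
  }
  dep$start_date <- as.Date(dep$start_date)
  dep$end_date <- as.Date(dep$end_date)
  dep
}

#' Write detection data to a directory
#'
#' Writes `Y.csv` (species x site), `V.csv`, and `metadata.yaml` (species,
#' sites, augmentation mask).
#'
#' @param data a [detection_data()] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_detection_data <- function(data, dir) {
  stopifnot(inherits(data, "detection_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data$Y, file.path(dir, "Y.csv"))
  write.csv(data.frame(station_id = data$sites, V = data$V),
            file.path(dir, "V.csv"), row.names = FALSE)
  yaml::write_yaml(list(species = data$species, sites = data$sites,
                        augmented = data$augmented),
                   file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' @rdname write_detection_data
#' @param dir directory written by [write_detection_data()].
#' @export
read_detection_data <- function(dir) {
  Y <- as.matrix(read.csv(file.path(dir, "Y.csv"), row.names = 1,
                          check.names = FALSE))
  Vtab <- read.csv(file.path(dir, "V.csv"), stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  detection_data(Y, setNames(Vtab$V, Vtab$station_id)[colnames(Y)],
                 augmented = as.logical(meta$augmented))
}
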