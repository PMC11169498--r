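test_that("stations within 500 m merge into independent stations (55 -> 50)", {
  set.seed(12)
  dep <- station_fixture_55()
  merged <- merge_stations(dep, 500)
  expect_equal(nrow(merged$deployments), 50)
  expect_equal(nrow(merged$mapping), 55)
  # merged pairs pooled their cameras and kept the centroid
  pair <- merged$deployments[grepl("\\+", merged$deployments$station_id), ]
  expect_equal(nrow(pair), 5)
  expect_equal(pair$n_cameras, rep(2L, 5))
  expect_true(all(pair$x %% 2000 == 150)) # centroid of 0/300 offset
})

test_that("distant stations are untouched and merging is idempotent", {
  dep <- station_fixture_55()
  dep <- dep[1:50, ] # the 2-km grid only
  merged <- merge_stations(dep, 500)
  expect_equal(merged$deployments$station_id, sort(dep$station_id))
  expect_equal(merged$mapping$old_id, merged$mapping$new_id)
  twice <- merge_stations(merge_stations(station_fixture_55())$deployments, 500)
  expect_equal(nrow(twice$deployments), 50)
})

test_that("merging follows transitive connected components", {
  dep <- data.frame(station_id = c("A", "B", "C"),
                    x = c(0, 400, 800) + 1e5, y = 1e5,
                    start_date = as.Date("2021-08-01"),
                    end_date = as.Date("2021-09-01"), n_cameras = 1L)
  # A-B 400 m, B-C 400 m, A-C 800 m: one station of three
  merged <- merge_stations(dep, 500)
  expect_equal(nrow(merged$deployments), 1)
  expect_equal(merged$deployments$station_id, "A+B+C")
  expect_equal(merged$deployments$n_cameras, 3L)
  # brute-force components oracle on random configurations
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    pts <- data.frame(station_id = sprintf("P%02d", 1:n),
                      x = runif(n, 0, 3000) + 1e5, y = runif(n, 0, 3000) + 1e5,
                      start_date = as.Date("2021-08-01"),
                      end_date = as.Date("2021-09-01"), n_cameras = 1L)
    d <- as.matrix(dist(pts[, c("x", "y")])) < 500
    # oracle: label propagation to a fixed point
    lab <- seq_len(n)
    repeat {
      new_lab <- vapply(seq_len(n), function(i) min(lab[d[i, ]]), numeric(1))
      if (identical(new_lab, lab)) break
      lab <- new_lab
    }
    expect_equal(nrow(merge_stations(pts, 500)$deployments),
                 length(unique(lab)))
  }
})

test_that("merge validation catches duplicates and geographic coordinates", {
  dep <- station_fixture_55()
  expect_error(merge_stations(rbind(dep, dep[1, ])), "duplicate")
  geo <- dep; geo$x <- geo$x / 1e5; geo$y <- geo$y / 1e5
  expect_error(merge_stations(geo), "geographic")
})

test_that("occasion counts follow ceil(days / occasion_days)", {
  mk <- function(days) data.frame(station_id = "S01", x = 1e5, y = 1e5,
                                  start_date = as.Date("2021-08-01"),
                                  end_date = as.Date("2021-08-01") + days - 1,
                                  n_cameras = 1L)
  expect_equal(unname(build_occasions(mk(95))$V), 19)
  expect_equal(unname(build_occasions(mk(92))$V), 19) # 18 full + 1 partial
  expect_equal(unname(build_occasions(mk(99))$V), 20)
  expect_equal(unname(build_occasions(mk(92), drop_partial = TRUE)$V), 18)
  cal <- build_occasions(mk(92))$calendars$S01
  expect_equal(nrow(cal), 19)
  expect_equal(cal$end[19], as.Date("2021-08-01") + 91) # clipped partial window
  bad <- mk(10); bad$end_date <- bad$start_date - 1
  expect_error(build_occasions(bad), "end_date before")
})

test_that("detection matrix collapses occasions and respects bounds", {
  dep <- data.frame(station_id = "S01", x = 1e5, y = 1e5,
                    start_date = as.Date("2021-08-01"),
                    end_date = as.Date("2021-08-25"), n_cameras = 1L)
  occ <- build_occasions(dep)
  rec <- data.frame(station_id = "S01", species = "tapir",
                    timestamp = as.POSIXct(c("2021-08-02 10:00:00",
                                             "2021-08-03 11:00:00",
                                             "2021-08-04 12:00:00"), tz = "UTC"))
  dd <- build_detection_matrix(rec, occ$calendars, occ$V)
  expect_equal(unname(dd$Y["tapir", "S01"]), 1L) # 3 records, 1 occasion
  empty <- build_detection_matrix(rec[0, ], occ$calendars, occ$V,
                                  species = "tapir")
  expect_true(all(empty$Y == 0))
})

test_that("detection matrix is invariant to record order and duplication", {
  set.seed(14)
  design <- study_design(n_sites = 6L, n_species = 4L,
                         forest_split = c(monospecific = 3L, polyspecific = 3L),
                         fire_split = c(burned = 3L, unburned = 3L),
                         active_days_range = c(15L, 20L))
  sim <- simulate_dataset(design, n_two_cameras = 1L)
  rec <- sim$record_table
  shuffled <- rec[sample(nrow(rec)), ]
  duplicated <- rbind(rec, rec[sample(nrow(rec), 5), ])
  base <- build_detection_matrix(rec, sim$calendars, sim$V, rownames(sim$Y))
  expect_identical(build_detection_matrix(shuffled, sim$calendars, sim$V,
                                          rownames(sim$Y))$Y, base$Y)
  expect_identical(build_detection_matrix(duplicated, sim$calendars, sim$V,
                                          rownames(sim$Y))$Y, base$Y)
})

test_that("records outside every occasion window are dropped with a warning", {
  dep <- data.frame(station_id = "S01", x = 1e5, y = 1e5,
                    start_date = as.Date("2021-08-01"),
                    end_date = as.Date("2021-08-10"), n_cameras = 1L)
  occ <- build_occasions(dep)
  rec <- data.frame(station_id = "S01", species = c("tapir", "tapir"),
                    timestamp = as.POSIXct(c("2021-08-02 10:00:00",
                                             "2021-09-20 10:00:00"), tz = "UTC"))
  expect_warning(dd <- build_detection_matrix(rec, occ$calendars, occ$V),
                 "dropped")
  expect_equal(attr(dd, "n_dropped"), 1L)
  expect_equal(sum(dd$Y), 1L)
  bad <- rec; bad$station_id <- "S99"
  expect_error(build_detection_matrix(bad, occ$calendars, occ$V), "unknown station")
})

test_that("augmentation appends flagged all-zero rows", {
  Y <- matrix(rbinom(14 * 6, 3, 0.3), 14, 6,
              dimnames = list(sprintf("sp%02d", 1:14), sprintf("S%02d", 1:6)))
  dd <- detection_data(Y, rep(5L, 6))
  aug <- augment_detections(dd, 8)
  expect_equal(nrow(aug$Y), 22) # 14 observed + 8 dummies
  expect_equal(sum(aug$augmented), 8)
  expect_true(all(aug$Y[aug$augmented, ] == 0))
  expect_identical(augment_detections(dd, 0), dd)
})

test_that("study-scale total effort lies in the printed activity range", {
  set.seed(16)
  sim <- simulate_dataset()
  expect_gte(sum(sim$V), ceiling(92 / 5) * 50)
  expect_lte(sum(sim$V), ceiling(99 / 5) * 50)
})

test_that("detection data round-trips through the directory format", {
  Y <- matrix(c(2L, 0L, 1L, 3L), 2, 2,
              dimnames = list(c("sp01", "sp02"), c("S01", "S02")))
  dd <- detection_data(Y, c(4L, 5L))
  dir <- tempfile()
  write_detection_data(dd, dir)
  back <- read_detection_data(dir)
  expect_identical(back$Y, dd$Y)
  expect_identical(back$V, dd$V)
  unlink(dir, recursive = TRUE)
})
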