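# Shared fixture builders; everything is generated in code at test time.

# Minimal covariate table with the columns the model matrices need.
toy_covariates <- function(J, fire = NULL, forest = NULL) {
  if (is.null(fire)) fire <- rep(c("burned", "unburned"), length.out = J)
  if (is.null(forest)) forest <- rep(c("monospecific", "polyspecific"), length.out = J)
  df <- data.frame(
    station_id = sprintf("S%02d", seq_len(J)),
    local_fire = fire, forest_type = forest,
    grassland = seq(0.1, 0.9, length.out = J),
    burned_area = seq(0.05, 0.95, length.out = J),
    n_cameras = rep(c(1L, 2L), length.out = J),
    stringsAsFactors = FALSE)
  for (col in c("grassland", "burned_area", "n_cameras")) {
    df[[paste0(col, "_std")]] <- as.numeric(scale(df[[col]]))
  }
  df
}

# 55 deployments: 50 locations on a 2-km grid, five of which have a twin
# 300 m away, so a 500-m merge yields exactly 50 independent stations.
station_fixture_55 <- function() {
  i <- 0:49
  base <- data.frame(
    station_id = sprintf("CT%02d", i + 1),
    x = (i %% 10) * 2000, y = (i %/% 10) * 2000,
    start_date = as.Date("2021-08-01"),
    end_date = as.Date("2021-08-01") + sample(91:98, 50, replace = TRUE),
    n_cameras = 1L, stringsAsFactors = FALSE)
  twins <- base[1:5, ]
  twins$station_id <- sprintf("CT%02dB", 1:5)
  twins$x <- twins$x + 300
  rbind(base, twins)
}

# A hand-built rn_fit carrying given Z (draws x species x sites) and w
# (draws x species) so derived-quantity recounts have a known truth.
fake_fit <- function(Z_draws, w_draws) {
  n <- dim(Z_draws)[1]; M <- dim(Z_draws)[2]; J <- dim(Z_draws)[3]
  species <- sprintf("sp%02d", seq_len(M))
  sites <- sprintf("S%02d", seq_len(J))
  Y <- matrix(0L, M, J, dimnames = list(species, sites))
  data <- detection_data(Y, rep(10L, J))
  pn <- c("mu_a0", paste0("w[", species, "]"))
  draws <- array(NA_real_, c(1, n, 1 + M), dimnames = list(NULL, NULL, pn))
  draws[1, , 1] <- 0
  for (i in seq_len(M)) draws[1, , 1 + i] <- w_draws[, i]
  Zarr <- array(NA_integer_, c(1, n, M, J),
                dimnames = list(NULL, NULL, species, sites))
  Zarr[1, , , ] <- Z_draws
  structure(list(draws = draws, Z = Zarr, data = data, covariates = NULL),
            class = "rn_fit")
}

# One OTU hit-table row.
otu_hit <- function(otu_id, taxon, identity, marker = "12S", length_bp = 137L,
                    reads = 20L, sample_id = "W01", water_class = "still",
                    coverage = 95) {
  data.frame(otu_id = otu_id, marker = marker, length_bp = length_bp,
             reads = reads, sample_id = sample_id, water_class = water_class,
             taxon = taxon, pct_identity = identity, pct_coverage = coverage,
             stringsAsFactors = FALSE)
}

# Random OTU hit table for property tests (well-formed binomial taxa).
random_otu_table <- function(n_otus = 12) {
  genera <- c("Akodon", "Mazama", "Panthera", "Tapirus", "Cerdocyon",
              "Holochilus", "Leopardus", "Puma")
  rows <- lapply(seq_len(n_otus), function(k) {
    n_hits <- sample(1:3, 1)
    do.call(rbind, lapply(seq_len(n_hits), function(h) {
      otu_hit(sprintf("otu%03d", k),
              paste(sample(genera, 1), sample(c("montensis", "rufa", "onca",
                                                "terrestris", "chacarius"), 1)),
              identity = round(runif(1, 85, 100), 1),
              marker = sample(c("12S", "16S"), 1),
              length_bp = sample(128:141, 1),
              reads = sample(0:40, 1),
              sample_id = sample(c("W01", "W02", "W03"), 1),
              water_class = sample(c("still", "running"), 1),
              coverage = round(runif(1, 80, 100), 1))
    }))
  })
  do.call(rbind, rows)
}

# Small fitted model shared by tests that only need a structurally valid
# posterior (built once per test run).
small_fit_cache <- new.env()
small_fit <- function() {
  if (is.null(small_fit_cache$fit)) {
    set.seed(2024)
    design <- study_design(n_sites = 12L, n_species = 5L, n_augmented = 2L,
                           forest_split = c(monospecific = 5L, polyspecific = 7L),
                           fire_split = c(burned = 5L, unburned = 7L),
                           active_days_range = c(20L, 25L))
    sim <- simulate_dataset(design, n_two_cameras = 3L)
    dd <- build_detection_matrix(sim$record_table, sim$calendars, sim$V,
                                 species = sim$observed)
    dd <- augment_detections(dd, 2L)
    small_fit_cache$fit <- suppressWarnings(run_mcmc(
      dd, sim$covariates, rn_priors(),
      mcmc_config(n_chains = 2L, n_iter = 800L, burn_in = 400L, thin = 2L,
                  seed = 99L)))
    small_fit_cache$sim <- sim
  }
  small_fit_cache$fit
}
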