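# Synthetic-community generator: study designs, community-distributed species
# parameters, latent abundances and timestamped camera-trap records with the
# statistical structure the multi-species Royle-Nichols model assumes. Every
# downstream stage of the package is testable against the truth stored here.

#' Community-level hyperparameters
#'
#' Means and standard deviations of the normal distributions that species
#' coefficients are drawn from (log-abundance scale `a0..a5`, logit-detection
#' scale `b0..b3`), plus the inclusion probability `omega` for augmented
#' species. Defaults describe a mammal community whose abundance declines
#' with burned-area proportion in monospecific forest (slope `a4 - a5 =
#' -0.8`) but is flat in polyspecific forest (`a4 + a5 = 0`), with modest
#' per-individual detection rates typical of unbaited camera traps.
#'
#' @param mu_a,sd_a length-6 community means / sds of abundance coefficients.
#' @param mu_b,sd_b length-4 community means / sds of detection coefficients.
#' @param omega inclusion probability in `[0, 1]`.
#' @return an object of class `community_hyperparams`.
#' @export
community_hyperparams <- function(mu_a = c(-0.7, 0.1, 0.3, 0.2, -0.4, 0.4),
                                  sd_a = c(0.8, 0.4, 0.4, 0.4, 0.4, 0.4),
                                  mu_b = c(-1.2, 0.2, 0.0, 0.3),
                                  sd_b = c(0.6, 0.3, 0.3, 0.3),
                                  omega = 0.6) {
  if (!all(is.finite(c(mu_a, sd_a, mu_b, sd_b, omega)))) {
    stop("hyperparameters must be finite")
  }
  stopifnot(length(mu_a) == 6L, length(sd_a) == 6L,
            length(mu_b) == 4L, length(sd_b) == 4L,
            all(sd_a >= 0), all(sd_b >= 0), omega >= 0, omega <= 1)
  structure(list(mu_a = mu_a, sd_a = sd_a, mu_b = mu_b, sd_b = sd_b,
                 omega = omega),
            class = "community_hyperparams")
}

#' Synthetic study design
#'
#' Defaults emulate the post-fire Pantanal survey skeleton: 50 independent
#' stations in two forest types (19 monospecific / 31 polyspecific), 20
#' burned / 30 unburned, cameras active 92--99 days binned into 5-day
#' occasions, and a community of 14 species analysed with 8 augmented
#' all-zero histories.
#'
#' @param n_sites number of independent stations.
#' @param n_species number of real species in the community.
#' @param n_augmented all-zero histories appended when fitting.
#' @param forest_split named counts for `monospecific` / `polyspecific`.
#' @param fire_split named counts for `burned` / `unburned`.
#' @param active_days_range inclusive range camera-active days are drawn from.
#' @param occasion_days occasion window length in days.
#' @param start_date deployment start date (all stations deployed together).
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_sites = 50L, n_species = 14L, n_augmented = 8L,
                         forest_split = c(monospecific = 19L, polyspecific = 31L),
                         fire_split = c(burned = 20L, unburned = 30L),
                         active_days_range = c(92L, 99L),
                         occasion_days = 5L,
                         start_date = as.Date("2021-08-01")) {
  stopifnot(n_sites >= 1, n_species >= 1, n_augmented >= 0, occasion_days >= 1)
  if (sum(forest_split) != n_sites) {
    stop("forest_split must sum to n_sites (", n_sites, ")")
  }
  if (sum(fire_split) != n_sites) {
    stop("fire_split must sum to n_sites (", n_sites, ")")
  }
  stopifnot(all(active_days_range >= 1),
            active_days_range[1] <= active_days_range[2])
  structure(list(n_sites = as.integer(n_sites),
                 n_species = as.integer(n_species),
                 n_augmented = as.integer(n_augmented),
                 forest_split = forest_split, fire_split = fire_split,
                 active_days_range = as.integer(active_days_range),
                 occasion_days = as.integer(occasion_days),
                 start_date = as.Date(start_date)),
            class = "study_design")
}

#' Draw species coefficients from the community distributions
#'
#' Each abundance coefficient `a[k]` of each species is an independent
#' `Normal(mu_a[k], sd_a[k])` draw, and likewise for detection coefficients.
#'
#' @param hyper a [community_hyperparams()] object.
#' @param n_species number of species to draw.
#' @return list with `a` (`n_species x 6`) and `b` (`n_species x 4`)
#'   coefficient matrices, species names `sp01`, `sp02`, ...
#' @export
draw_species_params <- function(hyper, n_species) {
  stopifnot(inherits(hyper, "community_hyperparams"), n_species >= 1)
  a <- sapply(1:6, function(k) rnorm(n_species, hyper$mu_a[k], hyper$sd_a[k]))
  b <- sapply(1:4, function(k) rnorm(n_species, hyper$mu_b[k], hyper$sd_b[k]))
  a <- matrix(a, n_species, 6); b <- matrix(b, n_species, 4)
  sp <- sprintf("sp%02d", seq_len(n_species))
  dimnames(a) <- list(sp, paste0("a", 0:5))
  dimnames(b) <- list(sp, paste0("b", 0:3))
  list(a = a, b = b, species = sp)
}

#' Simulate site covariates for a study design
#'
#' Forest type and fire treatment are assigned at random respecting the
#' design splits; grassland proportion is a `Beta(2, 5)` draw; burned-area
#' proportion is drawn from separate beta distributions at burned and
#' unburned sites (defaults `Beta(4, 2)` vs `Beta(1, 4)`) so the
#' forest-by-burned-area interaction is identifiable; a configurable number
#' of stations carry two cameras (merged stations). Continuous covariates
#' are returned raw and z-scored (`*_std` columns).
#'
#' @param design a [study_design()] object.
#' @param burned_area_beta_burned,burned_area_beta_unburned beta shape pairs
#'   for the burned-area proportion; set them equal for a zero-shift null.
#' @param grassland_beta beta shapes for grassland proportion.
#' @param n_two_cameras stations assigned two cameras.
#' @return a `data.frame` with one row per station: `station_id`, `x`, `y`,
#'   `local_fire`, `forest_type`, `grassland`, `burned_area`, `n_cameras`
#'   and standardized copies of the continuous fields.
#' @export
simulate_covariates <- function(design,
                                burned_area_beta_burned = c(4, 2),
                                burned_area_beta_unburned = c(1, 4),
                                grassland_beta = c(2, 5),
                                n_two_cameras = 5L) {
  stopifnot(inherits(design, "study_design"))
  J <- design$n_sites
  if (n_two_cameras > J) stop("n_two_cameras exceeds number of sites")
  forest <- sample(rep(names(design$forest_split), design$forest_split))
  fire <- sample(rep(names(design$fire_split), design$fire_split))
  grass <- rbeta(J, grassland_beta[1], grassland_beta[2])
  burned_area <- numeric(J)
  burned_area[fire == "burned"] <-
    rbeta(sum(fire == "burned"), burned_area_beta_burned[1],
          burned_area_beta_burned[2])
  burned_area[fire == "unburned"] <-
    rbeta(sum(fire == "unburned"), burned_area_beta_unburned[1],
          burned_area_beta_unburned[2])
  n_cam <- rep(1L, J)
  n_cam[sample.int(J, n_two_cameras)] <- 2L
  ncol_grid <- ceiling(sqrt(J))
  covs <- data.frame(
    station_id = sprintf("S%02d", seq_len(J)),
    x = ((seq_len(J) - 1L) %% ncol_grid) * 1000,
    y = ((seq_len(J) - 1L) %/% ncol_grid) * 1000,
    local_fire = fire, forest_type = forest,
    grassland = grass, burned_area = burned_area, n_cameras = n_cam,
    stringsAsFactors = FALSE)
  add_standardized(covs, c("grassland", "burned_area", "n_cameras"))
}

# Append z-scored copies (<col>_std) of the given columns.
add_standardized <- function(df, columns) {
  for (col in columns) {
    s <- sd(df[[col]])
    if (s == 0) stop("cannot standardize constant column: ", col)
    df[[paste0(col, "_std")]] <- (df[[col]] - mean(df[[col]])) / s
  }
  df
}

#' Simulate latent abundances and detection histories
#'
#' `Z[i, j] ~ Poisson(lambda_ij)` with `log(lambda)` from the abundance
#' regression, and `Y[i, j] ~ Binomial(V_j, 1 - (1 - r_ij)^Z[i, j])` with
#' `logit(r)` from the detection regression.
#'
#' @param params species coefficients from [draw_species_params()].
#' @param covariates site covariate table from [simulate_covariates()].
#' @param V integer vector of occasions per site.
#' @return list with integer matrices `Y` and `Z` (species x sites).
#' @export
simulate_detections <- function(params, covariates, V) {
  stopifnot(all(V >= 1), length(V) == nrow(covariates))
  lr <- lambda_r_matrices(params$a, params$b, covariates)
  loglam <- log(lr$lambda)
  if (any(abs(loglam) > 30)) {
    bad <- which(abs(loglam) > 30, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "|log lambda| > 30 for species %s at site %s; check coefficients a = (%s)",
      rownames(params$a)[bad[1]], covariates$station_id[bad[2]],
      paste(signif(params$a[bad[1], ], 3), collapse = ", ")))
  }
  M <- nrow(params$a); J <- nrow(covariates)
  Z <- matrix(rpois(M * J, lr$lambda), M, J)
  p <- rn_detection_prob(lr$r, Z)
  Y <- matrix(rbinom(M * J, rep(V, each = M), p), M, J)
  dimnames(Y) <- dimnames(Z) <-
    list(params$species, covariates$station_id)
  list(Y = Y, Z = Z)
}

#' Emit a timestamped camera-trap record table consistent with Y
#'
#' For each species-site cell with `Y` detected occasions, `Y` distinct
#' occasions are chosen and each receives one or more records with
#' timestamps uniform inside the occasion window, so rebuilding detection
#' histories from the records reproduces `Y` exactly.
#'
#' @param Y species x sites detection-frequency matrix.
#' @param calendars named list (per station) of occasion calendars as
#'   returned by [build_occasions()].
#' @return `data.frame` with `station_id`, `species`, `timestamp` (POSIXct,
#'   UTC), sorted by timestamp.
#' @export
emit_record_table <- function(Y, calendars) {
  stations <- colnames(Y)
  stopifnot(!is.null(stations), all(stations %in% names(calendars)))
  st_out <- sp_out <- list(); ts_out <- list()
  n_blk <- 0L
  for (j in seq_along(stations)) {
    cal <- calendars[[stations[j]]]
    if (any(Y[, j] > nrow(cal))) stop("Y exceeds occasion count at ", stations[j])
    for (i in seq_len(nrow(Y))) {
      y <- Y[i, j]
      if (y == 0) next
      occ <- sample.int(nrow(cal), y)
      n_rec <- 1L + rpois(y, 0.7)
      t0 <- as.numeric(as.POSIXct(cal$start[occ], tz = "UTC"))
      span <- as.numeric(as.POSIXct(cal$end[occ] + 1L, tz = "UTC")) - t0 - 1
      ts <- rep(t0, n_rec) + runif(sum(n_rec), 0, rep(span, n_rec))
      n_blk <- n_blk + 1L
      st_out[[n_blk]] <- rep(stations[j], sum(n_rec))
      sp_out[[n_blk]] <- rep(rownames(Y)[i], sum(n_rec))
      ts_out[[n_blk]] <- ts
    }
  }
  if (!n_blk) {
    return(data.frame(station_id = character(), species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC")))
  }
  res <- data.frame(station_id = unlist(st_out), species = unlist(sp_out),
                    timestamp = as.POSIXct(unlist(ts_out), tz = "UTC",
                                           origin = "1970-01-01"),
                    stringsAsFactors = FALSE)
  res[order(res$timestamp, res$station_id, res$species), , drop = FALSE]
}

#' Site summaries from the generating truth
#'
#' Richness and aggregated abundance per site computed directly from the
#' true latent abundance matrix (`sum_i 1[Z > 0]` and `sum_i Z`), in the
#' same schema as [site_summaries()]. Useful for calibration studies of the
#' post-hoc layer that do not need a model fit.
#'
#' @param sim a [simulate_dataset()] result.
#' @return `data.frame` with `site_id`, `mean_richness`, `mean_abundance`
#'   and the covariate columns the post-hoc battery uses.
#' @export
true_site_summaries <- function(sim) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  data.frame(site_id = sim$covariates$station_id,
             mean_richness = colSums(sim$Z > 0),
             mean_abundance = colSums(sim$Z),
             forest_type = sim$covariates$forest_type,
             local_fire = sim$covariates$local_fire,
             burned_area = sim$covariates$burned_area,
             row.names = NULL)
}

#' Generate a complete synthetic dataset
#'
#' Draws species coefficients from the community, simulates covariates,
#' deployments, latent abundances, detection histories and a record table,
#' and returns them together with the generating truth.
#'
#' @param design a [study_design()] object.
#' @param hyper a [community_hyperparams()] object.
#' @param emit_records build the timestamped record table (set `FALSE` when
#'   only `Y`/`Z` truth is needed, e.g. calibration studies).
#' @param ... passed to [simulate_covariates()].
#' @return an object of class `synthetic_dataset`: list with `covariates`,
#'   `deployments`, `calendars`, `V`, `params` (true coefficients), `Z`
#'   (true abundances), `Y`, `record_table`, `observed` (species with at
#'   least one detection), `design`, `hyper`.
#' @export
simulate_dataset <- function(design = study_design(),
                             hyper = community_hyperparams(),
                             emit_records = TRUE, ...) {
  stopifnot(inherits(design, "study_design"))
  params <- draw_species_params(hyper, design$n_species)
  covs <- simulate_covariates(design, ...)
  days <- sample(seq(design$active_days_range[1], design$active_days_range[2]),
                 design$n_sites, replace = TRUE)
  deployments <- data.frame(
    station_id = covs$station_id, x = covs$x, y = covs$y,
    start_date = design$start_date,
    end_date = design$start_date + days - 1L,
    n_cameras = covs$n_cameras, stringsAsFactors = FALSE)
  occ <- build_occasions(deployments, occasion_days = design$occasion_days)
  sim <- simulate_detections(params, covs, occ$V)
  rec <- if (emit_records) emit_record_table(sim$Y, occ$calendars) else NULL
  structure(list(covariates = covs, deployments = deployments,
                 calendars = occ$calendars, V = occ$V, params = params,
                 Z = sim$Z, Y = sim$Y, record_table = rec,
                 observed = rownames(sim$Y)[rowSums(sim$Y) > 0],
                 design = design, hyper = hyper),
            class = "synthetic_dataset")
}
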