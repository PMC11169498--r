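test_that("degenerate community (all sds zero) pins species at the means", {
  hyper <- community_hyperparams(sd_a = rep(0, 6), sd_b = rep(0, 4))
  set.seed(1)
  p <- draw_species_params(hyper, 7)
  for (i in 1:7) {
    expect_equal(unname(p$a[i, ]), hyper$mu_a)
    expect_equal(unname(p$b[i, ]), hyper$mu_b)
  }
})

test_that("species coefficients follow the community distribution (LLN)", {
  hyper <- community_hyperparams(mu_a = c(0, 0.1, 0.3, 0.2, -0.4, 0.4),
                                 sd_a = c(1, rep(0.4, 5)))
  set.seed(7)
  p <- draw_species_params(hyper, 10000)
  expect_lt(abs(mean(p$a[, 1]) - 0), 3 / sqrt(10000))
  expect_lt(abs(sd(p$a[, 1]) - 1), 0.05)
})

test_that("parameter draws are reproducible under a fixed seed", {
  hyper <- community_hyperparams()
  set.seed(11); p1 <- draw_species_params(hyper, 20)
  set.seed(11); p2 <- draw_species_params(hyper, 20)
  expect_identical(p1, p2)
})

test_that("hyperparameter validation rejects bad input", {
  expect_error(community_hyperparams(mu_a = c(0, 0, 0, 0, 0, Inf)), "finite")
  expect_error(community_hyperparams(sd_a = c(-1, 1, 1, 1, 1, 1)))
  expect_error(community_hyperparams(omega = 1.5))
})

test_that("simulated covariates respect the design splits", {
  set.seed(3)
  covs <- simulate_covariates(study_design())
  expect_equal(sum(covs$forest_type == "monospecific"), 19)
  expect_equal(sum(covs$forest_type == "polyspecific"), 31)
  expect_equal(sum(covs$local_fire == "burned"), 20)
  expect_equal(sum(covs$local_fire == "unburned"), 30)
  expect_true(all(covs$n_cameras %in% c(1L, 2L)))
  expect_true(all(covs$grassland >= 0 & covs$grassland <= 1))
  expect_true(all(covs$burned_area >= 0 & covs$burned_area <= 1))
  # standardized copies back-transform
  expect_equal(covs$grassland_std * sd(covs$grassland) + mean(covs$grassland),
               covs$grassland, tolerance = 1e-12)
  expect_error(simulate_covariates(
    study_design(forest_split = c(monospecific = 10L, polyspecific = 10L))),
    "sum to n_sites")
})

test_that("zero burned-area shift gives equal distributions across treatments", {
  set.seed(5)
  design <- study_design(n_sites = 2000L,
                         forest_split = c(monospecific = 1000L, polyspecific = 1000L),
                         fire_split = c(burned = 1000L, unburned = 1000L))
  covs <- simulate_covariates(design,
                              burned_area_beta_burned = c(2, 2),
                              burned_area_beta_unburned = c(2, 2))
  d <- abs(mean(covs$burned_area[covs$local_fire == "burned"]) -
             mean(covs$burned_area[covs$local_fire == "unburned"]))
  expect_lt(d, 3 * sqrt(2 * 0.05 / 1000)) # 3 SEs of a Beta(2,2) mean difference
})

test_that("detection simulation honours the model's degenerate limits", {
  covs <- toy_covariates(10)
  hyper0 <- community_hyperparams(mu_b = c(-30, 0, 0, 0), sd_b = rep(0, 4),
                                  sd_a = rep(0, 6))
  set.seed(2); p <- draw_species_params(hyper0, 3)
  sim <- simulate_detections(p, covs, V = rep(10L, 10))
  expect_true(all(sim$Y == 0)) # r ~ 0: nothing is ever detected
  hyperZ <- community_hyperparams(mu_a = c(-29, 0, 0, 0, 0, 0),
                                  sd_a = rep(0, 6), sd_b = rep(0, 4))
  set.seed(2); p <- draw_species_params(hyperZ, 3)
  sim <- simulate_detections(p, covs, V = rep(10L, 10))
  expect_true(all(sim$Z == 0)) # lambda ~ 0: nobody is there
  expect_true(all(sim$Y == 0))
})

test_that("latent abundance matches its Poisson mean by Monte Carlo", {
  # lambda = 1 for every species-site: 200 identical species x 500 sites
  covs <- toy_covariates(500)
  hyper <- community_hyperparams(mu_a = rep(0, 6), sd_a = rep(0, 6),
                                 mu_b = c(0, 0, 0, 0), sd_b = rep(0, 4))
  set.seed(9)
  p <- draw_species_params(hyper, 200)
  sim <- simulate_detections(p, covs, V = rep(5L, 500))
  expect_lt(abs(mean(sim$Z) - 1), 3 * sqrt(1 / 1e5))
})

test_that("lambda overflow is reported with the offending coefficients", {
  covs <- toy_covariates(4)
  p <- list(a = matrix(c(40, 0, 0, 0, 0, 0), 1, 6), b = matrix(0, 1, 4),
            species = "sp01")
  rownames(p$a) <- rownames(p$b) <- "sp01"
  expect_error(simulate_detections(p, covs, V = rep(5L, 4)),
               "log lambda.*sp01")
})

test_that("record emission round-trips through detection-history construction", {
  set.seed(21)
  design <- study_design(n_sites = 8L, n_species = 5L,
                         forest_split = c(monospecific = 3L, polyspecific = 5L),
                         fire_split = c(burned = 4L, unburned = 4L),
                         active_days_range = c(18L, 23L))
  sim <- simulate_dataset(design, n_two_cameras = 2L)
  expect_true(all(sim$Y <= matrix(sim$V, nrow(sim$Y), length(sim$V), byrow = TRUE)))
  expect_true(all(sim$Z >= 0))
  expect_true(all(sim$Y[sim$Z == 0] == 0))
  rebuilt <- build_detection_matrix(sim$record_table, sim$calendars, sim$V,
                                    species = rownames(sim$Y))
  expect_identical(unname(rebuilt$Y), unname(sim$Y))
  # every detected occasion got at least one record
  expect_gte(nrow(sim$record_table), sum(sim$Y))
})

test_that("empty detection matrix emits an empty record table", {
  cal <- build_occasions(data.frame(station_id = "S01", x = 1e5, y = 1e5,
                                    start_date = as.Date("2021-08-01"),
                                    end_date = as.Date("2021-08-20"),
                                    n_cameras = 1L))
  Y <- matrix(0L, 2, 1, dimnames = list(c("a", "b"), "S01"))
  rec <- emit_record_table(Y, cal$calendars)
  expect_equal(nrow(rec), 0)
})

test_that("degenerate single-species detection frequency matches the analytic law", {
  # P(Y = 0) = sum_z Pois(z; lambda) (1-r)^(zV) under the RN model
  lambda <- 0.8; r <- 0.35; V <- 6L
  covs <- toy_covariates(400)
  hyper <- community_hyperparams(mu_a = c(log(lambda), 0, 0, 0, 0, 0),
                                 sd_a = rep(0, 6),
                                 mu_b = c(qlogis(r), 0, 0, 0), sd_b = rep(0, 4))
  set.seed(31)
  p <- draw_species_params(hyper, 100)
  sim <- simulate_detections(p, covs, V = rep(V, 400))
  p0_hat <- mean(sim$Y == 0)
  p0 <- sum(dpois(0:200, lambda) * (1 - r)^((0:200) * V))
  se <- sqrt(p0 * (1 - p0) / length(sim$Y))
  expect_lt(abs(p0_hat - p0), 3 * se)
})
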