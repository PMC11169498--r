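row_of <- function(fire = "burned", forest = "polyspecific", g = 0.3,
                   ba = 0.5, nc = 1.2) {
  list(local_fire = fire, forest_type = forest, grassland_std = g,
       burned_area_std = ba, n_cameras_std = nc)
}

test_that("log-lambda is the documented linear predictor", {
  expect_equal(log_lambda(c(1.5, 0, 0, 0, 0, 0), row_of()), 1.5)
  # interaction only: forest = +1 (poly), burned_area = 0.5
  expect_equal(log_lambda(c(0, 0, 0, 0, 0, 1),
                          row_of(forest = "polyspecific", ba = 0.5)), 0.5)
  set.seed(41)
  for (rep in 1:20) {
    a <- rnorm(6)
    x <- row_of(fire = sample(c("burned", "unburned"), 1),
                forest = sample(c("monospecific", "polyspecific"), 1),
                g = rnorm(1), ba = rnorm(1))
    fire <- if (x$local_fire == "burned") -1 else 1
    forest <- if (x$forest_type == "monospecific") -1 else 1
    oracle <- sum(a * c(1, fire, forest, x$grassland_std, x$burned_area_std,
                        forest * x$burned_area_std))
    expect_equal(log_lambda(a, x), oracle, tolerance = 1e-12)
  }
})

test_that("detection rate is the inverse-logit regression", {
  expect_equal(detection_rate(c(0, 0, 0, 0), row_of()), 0.5)
  expect_lt(detection_rate(c(-30, 0, 0, 0), row_of()), 1e-12)
  set.seed(43)
  for (rep in 1:20) {
    b <- rnorm(4)
    x <- row_of(fire = sample(c("burned", "unburned"), 1), nc = rnorm(1))
    fire <- if (x$local_fire == "burned") -1 else 1
    forest <- if (x$forest_type == "monospecific") -1 else 1
    eta <- sum(b * c(1, fire, forest, x$n_cameras_std))
    expect_equal(detection_rate(b, x), 1 / (1 + exp(-eta)), tolerance = 1e-12)
  }
})

test_that("abundance-induced detection probability follows 1 - (1-r)^Z", {
  expect_equal(rn_detection_prob(0.3, 0), 0)
  expect_equal(rn_detection_prob(0.3, 1), 0.3)
  expect_equal(rn_detection_prob(0.5, 2), 0.75)
  # stable for tiny r, large Z
  expect_equal(rn_detection_prob(1e-12, 1e6), -expm1(1e6 * log1p(-1e-12)))
})

test_that("site-species log-likelihood matches the binomial pmf", {
  expect_equal(site_species_loglik(0, 5, 0.4, 0), 0) # absent, undetected
  expect_equal(site_species_loglik(1, 5, 0.4, 0), -Inf) # absent but detected
  p <- rn_detection_prob(0.3, 2) # = 0.51
  expect_equal(site_species_loglik(4, 19, 0.3, 2), dbinom(4, 19, 0.51, log = TRUE),
               tolerance = 1e-12)
})

test_that("the latent-abundance conditional is a normalized pmf", {
  pmf <- z_conditional_pmf(1.7, 0.35, 3, 10, 50)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  # full house of detections with near-certain detection: Z = 0 impossible
  pmf2 <- z_conditional_pmf(1.0, 0.99, 10, 10, 50)
  expect_equal(pmf2[1], 0)
  expect_gt(sum(pmf2[-1]), 0.999999)
})

test_that("the compiled Z sampler matches the enumerated conditional (chi-square)", {
  set.seed(51)
  cases <- list(c(lambda = 1.3, r = 0.4, Y = 3, V = 6),
                c(lambda = 0.5, r = 0.15, Y = 0, V = 19),
                c(lambda = 4.0, r = 0.6, Y = 10, V = 12))
  for (cs in cases) {
    n <- 20000
    draws <- firemsom:::.rn_z_draws(cs["lambda"], cs["r"], cs["Y"], cs["V"], 30L, n)
    pmf <- z_conditional_pmf(cs["lambda"], cs["r"], cs["Y"], cs["V"], 30L)
    # pool bins with small expectation
    keep <- pmf * n >= 5
    obs <- tabulate(draws + 1L, nbins = 31)
    o <- c(obs[keep], sum(obs[!keep]))
    e <- c(pmf[keep], sum(pmf[!keep])) * n
    nz <- e > 0
    stat <- sum((o[nz] - e[nz])^2 / e[nz])
    expect_gt(pchisq(stat, df = sum(nz) - 1, lower.tail = FALSE), 0.001)
  }
})

test_that("the all-zero-history probability matches its closed form", {
  # sum_z Pois(z; lambda) s^z = exp(lambda (s - 1)), s = (1-r)^V
  for (cs in list(c(0.7, 0.3, 10), c(2.1, 0.05, 19), c(0.2, 0.8, 5))) {
    lambda <- cs[1]; r <- cs[2]; V <- cs[3]
    s <- (1 - r)^V
    expect_equal(firemsom:::all_zero_prob(lambda, r, V, 50),
                 exp(lambda * (s - 1)), tolerance = 1e-10)
  }
})

test_that("inclusion probability follows Bayes rule on a two-site toy", {
  omega <- 0.37; lambda <- c(0.9, 1.4); r <- c(0.25, 0.4); V <- c(6, 8)
  L <- prod(vapply(1:2, function(j)
    firemsom:::all_zero_prob(lambda[j], r[j], V[j], 50), numeric(1)))
  q_oracle <- omega * L / (omega * L + (1 - omega))
  expect_equal(firemsom:::inclusion_prob(omega, log(L)), q_oracle,
               tolerance = 1e-10)
  expect_equal(firemsom:::inclusion_prob(0, log(L)), 0)
  # uninformative data (r = 0 so L = 1): posterior inclusion equals omega
  expect_equal(firemsom:::inclusion_prob(omega, 0), omega, tolerance = 1e-12)
})

test_that("reference R updates preserve structural invariants", {
  set.seed(55)
  covs <- toy_covariates(5)
  Y <- matrix(c(2L, 0L, 1L, 0L, 0L,
                0L, 0L, 0L, 0L, 0L), 2, 5, byrow = TRUE,
              dimnames = list(c("sp01", "aug01"), covs$station_id))
  dd <- detection_data(Y, rep(6L, 5), augmented = c(FALSE, TRUE))
  state <- list(a = matrix(rnorm(12, 0, 0.3), 2, 6),
                b = matrix(rnorm(8, 0, 0.3), 2, 4),
                mu_a = rep(0, 6), sd_a = rep(1, 6),
                mu_b = rep(0, 4), sd_b = rep(1, 4),
                omega = 0.5, Z = matrix(pmax(Y, 1L), 2, 5), w = c(1L, 1L))
  for (it in 1:20) {
    state <- update_w_omega(state, dd, covs)
    state <- update_coefficients(state, dd, covs)
    state <- update_Z(state, dd, covs)
    expect_true(all(state$Z >= 0))
    expect_equal(state$w[1], 1L) # observed species stay included
    expect_true(state$omega >= 0 && state$omega <= 1)
    expect_true(all(is.finite(state$a)) && all(is.finite(state$b)))
  }
})

test_that("community-mean Gibbs draw matches its conjugate moments", {
  set.seed(57)
  coefs <- rnorm(22, 1.2, 0.7)
  sd_k <- 0.7; mu_sd <- sqrt(10)
  prec <- length(coefs) / sd_k^2 + 1 / mu_sd^2
  m <- (sum(coefs) / sd_k^2) / prec
  v <- 1 / prec
  draws <- replicate(20000, firemsom:::hyper_mean_draw(coefs, sd_k, mu_sd))
  expect_lt(abs(mean(draws) - m), 3 * sqrt(v / 20000))
  expect_lt(abs(var(draws) / v - 1), 0.05)
})

test_that("marginal likelihood separates over cells", {
  set.seed(59)
  lambda <- matrix(runif(6, 0.2, 2), 2, 3)
  r <- matrix(runif(6, 0.1, 0.6), 2, 3)
  Y <- matrix(c(1L, 0L, 2L, 0L, 3L, 1L), 2, 3)
  V <- c(4L, 4L, 4L)
  ll <- rn_marginal_loglik(lambda, r, Y, V, z_max = 40)
  by_cell <- sum(vapply(1:2, function(i) sum(vapply(1:3, function(j) {
    z <- 0:40
    log(sum(dpois(z, lambda[i, j]) *
              dbinom(Y[i, j], V[j], rn_detection_prob(r[i, j], z))))
  }, numeric(1))), numeric(1)))
  expect_equal(ll, by_cell, tolerance = 1e-12)
})
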