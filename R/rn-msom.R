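# Hierarchical multi-species Royle-Nichols model: likelihood components,
# priors, and reference (pure-R) Gibbs/Metropolis updates. run_mcmc() drives
# the compiled sampler in src/; the functions here define the model and serve
# as the oracle-testable reference path.

#' Covariate coding used by the abundance and detection regressions
#'
#' Categorical covariates enter the model effect-coded so that coefficient
#' signs match the convention "negative = monospecific / burned, positive =
#' polyspecific / unburned": `local_fire` is -1 for burned and +1 for
#' unburned sites; `forest_type` is -1 for monospecific and +1 for
#' polyspecific stands.
#'
#' @param x character vector of levels (`"burned"`/`"unburned"` or
#'   `"monospecific"`/`"polyspecific"`).
#' @return numeric vector in \{-1, +1\}.
#' @export
encode_fire <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), c("burned", "unburned"))
  if (length(bad)) stop("unknown local_fire level(s): ", paste(bad, collapse = ", "))
  ifelse(x == "burned", -1, 1)
}

#' @rdname encode_fire
#' @export
encode_forest <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), c("monospecific", "polyspecific"))
  if (length(bad)) stop("unknown forest_type level(s): ", paste(bad, collapse = ", "))
  ifelse(x == "monospecific", -1, 1)
}

# Slope design matrices (no intercept column; a0/b0 are handled separately).
# Abundance: fire, forest, grassland, burned area, forest x burned area.
# Detection: fire, forest, standardized camera count.
model_matrices <- function(covariates) {
  fire <- encode_fire(covariates$local_fire)
  forest <- encode_forest(covariates$forest_type)
  gr <- covariates$grassland_std
  ba <- covariates$burned_area_std
  nc <- covariates$n_cameras_std
  if (is.null(gr) || is.null(ba) || is.null(nc)) {
    stop("covariates must carry grassland_std, burned_area_std and n_cameras_std columns")
  }
  Xa <- cbind(fire = fire, forest = forest, grassland = gr,
              burned_area = ba, forest_x_burned = forest * ba)
  Xd <- cbind(fire = fire, forest = forest, n_cameras = nc)
  list(Xa = Xa, Xd = Xd)
}

#' Linear predictor of log abundance for one species
#'
#' `log(lambda_ij) = a0 + a1*fire + a2*forest + a3*grassland + a4*burned_area
#' + a5*forest*burned_area` with the coding of [encode_fire()].
#'
#' @param a numeric length-6 coefficient vector `(a0, a1, ..., a5)`.
#' @param x a single covariate row (list or one-row data frame) with
#'   `local_fire`, `forest_type`, `grassland_std`, `burned_area_std`.
#' @return scalar log abundance rate.
#' @export
log_lambda <- function(a, x) {
  stopifnot(length(a) == 6L, all(is.finite(a)))
  fire <- encode_fire(x$local_fire)
  forest <- encode_forest(x$forest_type)
  a[1] + a[2] * fire + a[3] * forest + a[4] * x$grassland_std +
    a[5] * x$burned_area_std + a[6] * forest * x$burned_area_std
}

#' Per-individual detection rate for one species
#'
#' `logit(r_ij) = b0 + b1*fire + b2*forest + b3*n_cameras` (camera count
#' standardized).
#'
#' @param b numeric length-4 coefficient vector `(b0, b1, b2, b3)`.
#' @param x a single covariate row with `local_fire`, `forest_type`,
#'   `n_cameras_std`.
#' @return detection rate in (0, 1).
#' @export
detection_rate <- function(b, x) {
  stopifnot(length(b) == 4L, all(is.finite(b)))
  fire <- encode_fire(x$local_fire)
  forest <- encode_forest(x$forest_type)
  plogis(b[1] + b[2] * fire + b[3] * forest + b[4] * x$n_cameras_std)
}

# lambda (M x J) and r (M x J) for a full coefficient set.
lambda_r_matrices <- function(a, b, covariates) {
  mm <- model_matrices(covariates)
  eta_a <- a[, 1] + a[, -1, drop = FALSE] %*% t(mm$Xa)
  eta_d <- b[, 1] + b[, -1, drop = FALSE] %*% t(mm$Xd)
  list(lambda = exp(eta_a), r = plogis(eta_d))
}

#' Royle-Nichols site-level detection probability
#'
#' The chance that at least one of `Z` independently detectable individuals
#' is recorded during a visit: `p = 1 - (1 - r)^Z`, computed in log space so
#' small `r` with large `Z` does not underflow.
#'
#' @param r per-individual detection rate(s) in `[0, 1]`.
#' @param Z non-negative integer abundance(s).
#' @return detection probability, same length as the recycled inputs.
#' @export
rn_detection_prob <- function(r, Z) {
  stopifnot(all(r >= 0 & r <= 1), all(Z >= 0))
  -expm1(Z * log1p(-r))
}

#' Log-likelihood of one species-by-site detection history
#'
#' `Y ~ Binomial(V, 1 - (1 - r)^Z)`. Returns `-Inf` when `Z = 0` but
#' `Y > 0` (an absent species cannot be detected).
#'
#' @param Y occasions with a detection (0..V).
#' @param V number of occasions the station was active.
#' @param r per-individual detection rate.
#' @param Z latent abundance.
#' @return scalar log-likelihood.
#' @export
site_species_loglik <- function(Y, V, r, Z) {
  stopifnot(Y >= 0, Y <= V)
  dbinom(Y, V, rn_detection_prob(r, Z), log = TRUE)
}

#' Priors for the community model
#'
#' Weakly-informative defaults: community means `Normal(0, sd = sqrt(10))`,
#' community standard deviations `Uniform(0, 5)`, inclusion probability
#' `Omega ~ Uniform(0, 1)`, and latent abundance enumerated on `0..z_max`.
#'
#' @param mu_sd prior standard deviation of the community means.
#' @param sd_max upper bound of the uniform prior on community sds.
#' @param z_max truncation point for latent-abundance enumeration; posterior
#'   mass reaching `z_max` triggers a warning from the sampler.
#' @return an object of class `rn_priors`.
#' @export
rn_priors <- function(mu_sd = sqrt(10), sd_max = 5, z_max = 50L) {
  stopifnot(mu_sd > 0, sd_max > 0, z_max >= 1)
  structure(list(mu_sd = mu_sd, sd_max = sd_max, z_max = as.integer(z_max)),
            class = "rn_priors")
}

#' MCMC configuration
#'
#' Defaults follow the study protocol (3 chains, 100,000 iterations, 50,000
#' burn-in, thinning 100); recovery experiments in the package use a reduced
#' schedule (3 x 5,000 / 2,500 / 5).
#'
#' @param n_chains,n_iter,burn_in,thin standard MCMC schedule controls.
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @param adapt_interval batch length for proposal-scale adaptation during
#'   burn-in (adaptation freezes afterwards, preserving detailed balance).
#' @param target_accept target acceptance rate of the random-walk updates.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 100000L, burn_in = 50000L,
                        thin = 100L, seed = 1L, adapt_interval = 50L,
                        target_accept = 0.44) {
  stopifnot(n_chains >= 1, burn_in < n_iter, thin >= 1,
            (n_iter - burn_in) %% thin == 0 || TRUE)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept),
            class = "mcmc_config")
}

#' Full conditional of latent abundance at one species-site cell
#'
#' Normalized probability mass over `Z = 0..z_max`, proportional to
#' `Poisson(Z; lambda) * Binomial(Y; V, 1 - (1-r)^Z)`.
#'
#' @param lambda Poisson abundance rate.
#' @param r per-individual detection rate.
#' @param Y,V detection history cell.
#' @param z_max enumeration bound.
#' @return numeric vector of length `z_max + 1` summing to 1.
#' @export
z_conditional_pmf <- function(lambda, r, Y, V, z_max = 50L) {
  z <- 0:z_max
  lw <- dpois(z, lambda, log = TRUE) +
    dbinom(Y, V, rn_detection_prob(r, z), log = TRUE)
  m <- max(lw)
  if (!is.finite(m)) stop("degenerate latent-abundance conditional (all mass zero)")
  wts <- exp(lw - m)
  wts / sum(wts)
}

# Truncated Poisson prior pmf on 0..z_max, stable for any finite lambda.
z_prior_pmf <- function(lambda, z_max) {
  lw <- dpois(0:z_max, lambda, log = TRUE)
  wts <- exp(lw - max(lw))
  wts / sum(wts)
}

# Probability of an all-zero history for one species at one site,
# marginalizing Z over the truncated prior on 0..z_max (log-space, stable
# for any finite lambda).
all_zero_prob <- function(lambda, r, V, z_max) {
  z <- 0:z_max
  lp <- dpois(z, lambda, log = TRUE)
  lw <- lp + z * V * log1p(-r)
  m1 <- max(lw); m2 <- max(lp)
  exp((m1 + log(sum(exp(lw - m1)))) - (m2 + log(sum(exp(lp - m2)))))
}

#' Marginal log-likelihood of the detection data given species parameters
#'
#' Latent abundance is summed out cell by cell (cells are conditionally
#' independent given the parameters):
#' `sum_ij log sum_z Poisson(z; lambda_ij) Binomial(Y_ij; V_j, 1-(1-r_ij)^z)`.
#' Used as the building block that the exhaustive-enumeration oracle checks.
#'
#' @param lambda,r M x J matrices of abundance rates and detection rates.
#' @param Y M x J detection-frequency matrix.
#' @param V length-J occasion counts.
#' @param z_max enumeration bound.
#' @return scalar log-likelihood.
#' @export
rn_marginal_loglik <- function(lambda, r, Y, V, z_max = 50L) {
  stopifnot(all(dim(lambda) == dim(Y)), all(dim(r) == dim(Y)),
            length(V) == ncol(Y))
  z <- 0:z_max
  total <- 0
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      wts <- dpois(z, lambda[i, j]) *
        dbinom(Y[i, j], V[j], rn_detection_prob(r[i, j], z))
      total <- total + log(sum(wts))
    }
  }
  total
}

# ---------------------------------------------------------------------------
# Reference (R) Metropolis-within-Gibbs updates. These operate on a `state`
# list with elements a (M x 6), b (M x 4), mu_a, sd_a, mu_b, sd_b, omega,
# Z (M x J), w (length M), and mirror the compiled sampler step for step.
# ---------------------------------------------------------------------------

#' One Gibbs update of the latent abundance matrix
#'
#' Species currently included (`w = 1`) draw each `Z[i, j]` from its
#' enumerated full conditional; excluded species draw from the truncated
#' Poisson prior.
#'
#' @param state sampler state list (see Details in [run_mcmc()]).
#' @param data a `detection_data` object.
#' @param covariates site covariate table.
#' @param priors an [rn_priors()] object.
#' @return the state with a new `Z`.
#' @export
update_Z <- function(state, data, covariates, priors = rn_priors()) {
  lr <- lambda_r_matrices(state$a, state$b, covariates)
  M <- nrow(data$Y); J <- ncol(data$Y)
  zmax <- priors$z_max
  for (i in seq_len(M)) {
    for (j in seq_len(J)) {
      if (state$w[i] == 1) {
        pmf <- z_conditional_pmf(lr$lambda[i, j], lr$r[i, j],
                                 data$Y[i, j], data$V[j], zmax)
      } else {
        pmf <- z_prior_pmf(lr$lambda[i, j], zmax)
      }
      state$Z[i, j] <- sample.int(zmax + 1L, 1L, prob = pmf) - 1L
    }
  }
  state
}

#' One partially-collapsed update of inclusion indicators and Omega
#'
#' For each augmented species the inclusion indicator is drawn from its
#' conditional with latent abundance marginalized out,
#' `q = Omega L / (Omega L + 1 - Omega)` where `L` is the probability of an
#' all-zero history, and `Z` for that species is immediately redrawn from the
#' conditional matching the new `w`. `Omega` then gets its conjugate
#' `Beta(1 + sum(w), 1 + M - sum(w))` draw.
#'
#' @inheritParams update_Z
#' @return the state with new `w`, `omega` (and refreshed `Z` rows for
#'   augmented species).
#' @export
update_w_omega <- function(state, data, covariates, priors = rn_priors()) {
  lr <- lambda_r_matrices(state$a, state$b, covariates)
  M <- nrow(data$Y)
  zmax <- priors$z_max
  for (i in which(data$augmented)) {
    logL <- sum(vapply(seq_along(data$V), function(j) {
      log(all_zero_prob(lr$lambda[i, j], lr$r[i, j], data$V[j], zmax))
    }, numeric(1)))
    q <- inclusion_prob(state$omega, logL)
    state$w[i] <- rbinom(1L, 1L, q)
    for (j in seq_along(data$V)) {
      if (state$w[i] == 1) {
        pmf <- z_conditional_pmf(lr$lambda[i, j], lr$r[i, j], 0L,
                                 data$V[j], zmax)
      } else {
        pmf <- z_prior_pmf(lr$lambda[i, j], zmax)
      }
      state$Z[i, j] <- sample.int(zmax + 1L, 1L, prob = pmf) - 1L
    }
  }
  state$omega <- rbeta(1, 1 + sum(state$w), 1 + M - sum(state$w))
  state
}

# Conditional inclusion probability on the probability scale, stable for
# very negative log-likelihoods.
inclusion_prob <- function(omega, logL) {
  if (omega <= 0) return(0)
  if (omega >= 1) return(1)
  plogis(qlogis(omega) + logL)
}

#' One sweep of coefficient and hyperparameter updates
#'
#' Included species update each regression coefficient by random-walk
#' Metropolis on its full conditional given `Z` and `w`; excluded species
#' draw coefficients exactly from the community distributions (their data
#' carry no information). Community means get conjugate normal Gibbs draws;
#' community standard deviations get random-walk Metropolis under the
#' `Uniform(0, sd_max)` prior.
#'
#' @inheritParams update_Z
#' @param scales list with `a`, `b` (M x K proposal sd matrices) and
#'   `sd_a`, `sd_b` (hyper-sd proposal sds); defaults are moderate constants.
#' @return the state with new coefficients and hyperparameters.
#' @export
update_coefficients <- function(state, data, covariates, priors = rn_priors(),
                                scales = NULL) {
  mm <- model_matrices(covariates)
  M <- nrow(data$Y)
  if (is.null(scales)) {
    scales <- list(a = matrix(0.3, M, 6), b = matrix(0.3, M, 4),
                   sd_a = rep(0.3, 6), sd_b = rep(0.3, 4))
  }
  Xa1 <- cbind(1, mm$Xa); Xd1 <- cbind(1, mm$Xd)
  for (i in seq_len(M)) {
    if (state$w[i] == 0) {
      state$a[i, ] <- rnorm(6, state$mu_a, state$sd_a)
      state$b[i, ] <- rnorm(4, state$mu_b, state$sd_b)
      next
    }
    for (k in 1:6) {
      prop <- state$a[i, ]
      prop[k] <- prop[k] + rnorm(1, 0, scales$a[i, k])
      cur_eta <- drop(Xa1 %*% state$a[i, ]); new_eta <- drop(Xa1 %*% prop)
      # truncated-Poisson likelihood of Z (support 0..z_max): the
      # normalizer ppois(z_max, lambda) matters once lambda nears z_max
      delta <- sum(state$Z[i, ] * new_eta - exp(new_eta) -
                     ppois(priors$z_max, exp(new_eta), log.p = TRUE)) -
        sum(state$Z[i, ] * cur_eta - exp(cur_eta) -
              ppois(priors$z_max, exp(cur_eta), log.p = TRUE)) +
        dnorm(prop[k], state$mu_a[k], state$sd_a[k], log = TRUE) -
        dnorm(state$a[i, k], state$mu_a[k], state$sd_a[k], log = TRUE)
      if (log(runif(1)) < delta) state$a[i, ] <- prop
    }
    for (k in 1:4) {
      prop <- state$b[i, ]
      prop[k] <- prop[k] + rnorm(1, 0, scales$b[i, k])
      cur_p <- rn_detection_prob(plogis(drop(Xd1 %*% state$b[i, ])), state$Z[i, ])
      new_p <- rn_detection_prob(plogis(drop(Xd1 %*% prop)), state$Z[i, ])
      delta <- sum(dbinom(data$Y[i, ], data$V, new_p, log = TRUE)) -
        sum(dbinom(data$Y[i, ], data$V, cur_p, log = TRUE)) +
        dnorm(prop[k], state$mu_b[k], state$sd_b[k], log = TRUE) -
        dnorm(state$b[i, k], state$mu_b[k], state$sd_b[k], log = TRUE)
      if (is.finite(delta) && log(runif(1)) < delta) state$b[i, ] <- prop
    }
  }
  for (k in 1:6) {
    state$mu_a[k] <- hyper_mean_draw(state$a[, k], state$sd_a[k], priors$mu_sd)
    state$sd_a[k] <- hyper_sd_draw(state$a[, k], state$mu_a[k], state$sd_a[k],
                                   scales$sd_a[k], priors$sd_max)
  }
  for (k in 1:4) {
    state$mu_b[k] <- hyper_mean_draw(state$b[, k], state$sd_b[k], priors$mu_sd)
    state$sd_b[k] <- hyper_sd_draw(state$b[, k], state$mu_b[k], state$sd_b[k],
                                   scales$sd_b[k], priors$sd_max)
  }
  state
}

# Conjugate draw for a community mean given species coefficients.
hyper_mean_draw <- function(coefs, sd_k, mu_sd) {
  prec <- length(coefs) / sd_k^2 + 1 / mu_sd^2
  rnorm(1, sum(coefs) / sd_k^2 / prec, sqrt(1 / prec))
}

# Random-walk Metropolis draw for a community sd under Uniform(0, sd_max).
hyper_sd_draw <- function(coefs, mu_k, sd_k, scale, sd_max) {
  prop <- sd_k + rnorm(1, 0, scale)
  if (prop <= 0 || prop >= sd_max) return(sd_k)
  delta <- sum(dnorm(coefs, mu_k, prop, log = TRUE)) -
    sum(dnorm(coefs, mu_k, sd_k, log = TRUE))
  if (log(runif(1)) < delta) prop else sd_k
}
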