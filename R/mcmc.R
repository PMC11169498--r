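# run_mcmc(): multi-chain driver around the compiled single-chain sampler,
# plus the rn_fit container and draw-extraction helpers.

#' Fit the multi-species Royle-Nichols model by MCMC
#'
#' Runs `config$n_chains` Metropolis-within-Gibbs chains from over-dispersed
#' random starts, discards burn-in, thins, and retains the community
#' hyperparameters, `Omega`, species coefficients, inclusion indicators `w`
#' and latent abundance draws `Z`. Fully reproducible given `config$seed`.
#'
#' @param data a [detection_data()] object (augment first with
#'   [augment_detections()] if community-size estimation is wanted).
#' @param covariates site covariate table (rows aligned with `data$sites`)
#'   carrying `local_fire`, `forest_type`, `grassland_std`,
#'   `burned_area_std`, `n_cameras_std`.
#' @param priors an [rn_priors()] object.
#' @param config an [mcmc_config()] object.
#' @return an object of class `rn_fit` with elements `draws` (array chains x
#'   retained x parameters, named), `Z` (array chains x retained x species x
#'   sites), `accept_rate` per chain, `max_zmax_tail`, and the inputs.
#' @export
run_mcmc <- function(data, covariates, priors = rn_priors(),
                     config = mcmc_config()) {
  stopifnot(inherits(data, "detection_data"),
            inherits(priors, "rn_priors"), inherits(config, "mcmc_config"))
  if (nrow(covariates) != ncol(data$Y)) {
    stop("covariate rows (", nrow(covariates), ") != sites (", ncol(data$Y), ")")
  }
  if ((config$n_iter - config$burn_in) %% config$thin != 0) {
    stop("(n_iter - burn_in) must be a multiple of thin")
  }
  mm <- model_matrices(covariates)
  M <- nrow(data$Y); J <- ncol(data$Y)
  if (max(data$Y) > priors$z_max) {
    stop("z_max (", priors$z_max, ") below maximum observed detection count")
  }
  set.seed(config$seed)
  n_ret <- (config$n_iter - config$burn_in) %/% config$thin
  pnames <- c(paste0("mu_a", 0:5), paste0("sd_a", 0:5),
              paste0("mu_b", 0:3), paste0("sd_b", 0:3), "omega",
              paste0(rep(paste0("a", 0:5), each = M), "[", data$species, "]"),
              paste0(rep(paste0("b", 0:3), each = M), "[", data$species, "]"),
              paste0("w[", data$species, "]"))
  draws <- array(NA_real_, c(config$n_chains, n_ret, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  Zdraws <- array(NA_integer_, c(config$n_chains, n_ret, M, J),
                  dimnames = list(NULL, NULL, data$species, data$sites))
  accept <- numeric(config$n_chains)
  max_tail <- 0
  for (ch in seq_len(config$n_chains)) {
    init <- draw_initial_state(data, covariates, priors)
    res <- .rn_chain(data$Y, data$V, mm$Xa, mm$Xd, data$augmented, init,
                     priors$mu_sd, priors$sd_max, priors$z_max,
                     config$n_iter, config$burn_in, config$thin,
                     config$adapt_interval, config$target_accept)
    draws[ch, , ] <- res$draws
    Zdraws[ch, , , ] <- array(res$Z, c(n_ret, M, J))
    accept[ch] <- res$accept_rate
    max_tail <- max(max_tail, res$max_zmax_tail)
  }
  if (max_tail > 1e-6) {
    warning(sprintf(
      "posterior mass at z_max reached %.2g (> 1e-6); consider raising z_max",
      max_tail))
  }
  if (any(accept < 0.05 | accept > 0.7)) {
    warning(sprintf("overall Metropolis acceptance rate outside [0.05, 0.7]: %s",
                    paste(signif(accept, 2), collapse = ", ")))
  }
  structure(list(draws = draws, Z = Zdraws, accept_rate = accept,
                 max_zmax_tail = max_tail, data = data,
                 covariates = covariates, priors = priors, config = config),
            class = "rn_fit")
}

# Over-dispersed random start with a guaranteed finite log-posterior:
# hyper means jittered, sds moderate, coefficients drawn from the start
# community shrunk toward it, Z initialized at max(Y, 1).
draw_initial_state <- function(data, covariates, priors, max_tries = 100L) {
  M <- nrow(data$Y); J <- ncol(data$Y)
  for (t in seq_len(max_tries)) {
    mu_a <- rnorm(6, 0, 1); sd_a <- runif(6, 0.3, 1.5)
    mu_b <- rnorm(4, 0, 1); sd_b <- runif(4, 0.3, 1.5)
    st <- list(a = sapply(1:6, function(k) mu_a[k] + 0.1 * rnorm(M, 0, sd_a[k])),
               b = sapply(1:4, function(k) mu_b[k] + 0.1 * rnorm(M, 0, sd_b[k])),
               mu_a = mu_a, sd_a = sd_a, mu_b = mu_b, sd_b = sd_b,
               omega = runif(1, 0.2, 0.9),
               Z = matrix(pmax(data$Y, 1L), M, J),
               w = rep(1L, M))
    st$a <- matrix(st$a, M, 6); st$b <- matrix(st$b, M, 4)
    lr <- lambda_r_matrices(st$a, st$b, covariates)
    ll <- sum(dpois(st$Z, lr$lambda, log = TRUE)) +
      sum(dbinom(data$Y, matrix(data$V, M, J, byrow = TRUE),
                 rn_detection_prob(lr$r, st$Z), log = TRUE))
    if (is.finite(ll)) return(st)
  }
  stop("could not find a finite-log-posterior start in ", max_tries, " tries")
}

#' @export
print.rn_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("rn_fit: %d chains x %d retained draws x %d parameters\n",
              d[1], d[2], d[3]))
  cat(sprintf("  %d species (%d augmented) x %d sites; acceptance %s\n",
              nrow(x$data$Y), sum(x$data$augmented), ncol(x$data$Y),
              paste(signif(x$accept_rate, 2), collapse = "/")))
  invisible(x)
}

#' Extract retained draws of one parameter
#'
#' @param fit an `rn_fit`.
#' @param parameter parameter name, e.g. `"mu_a5"` or `"a5[sp01]"`.
#' @param collapse if `TRUE` (default) return one pooled vector, else a
#'   chains x iterations matrix.
#' @return numeric vector or matrix of posterior draws.
#' @export
extract_draws <- function(fit, parameter, collapse = TRUE) {
  stopifnot(inherits(fit, "rn_fit"))
  if (!parameter %in% dimnames(fit$draws)[[3]]) {
    stop("unknown parameter: ", parameter)
  }
  m <- fit$draws[, , parameter, drop = FALSE]
  dim(m) <- dim(fit$draws)[1:2]
  if (collapse) as.vector(t(m)) else m
}

#' Parameter names of a fitted model
#' @param fit an `rn_fit`.
#' @param hyper_only return only community-level parameters and `omega`.
#' @return character vector.
#' @export
parameter_names <- function(fit, hyper_only = FALSE) {
  nm <- dimnames(fit$draws)[[3]]
  if (hyper_only) nm[grepl("^(mu_|sd_|omega)", nm)] else nm
}

#' Write posterior draws to a columnar CSV
#'
#' Long format with one row per retained draw of each parameter:
#' `chain, iteration, parameter, value`. Latent `Z` draws are omitted
#' (regenerate them by refitting with the stored seed).
#'
#' @param fit an `rn_fit`.
#' @param path output CSV path.
#' @param parameters subset of parameter names (default: all).
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(fit, path, parameters = NULL) {
  stopifnot(inherits(fit, "rn_fit"))
  if (is.null(parameters)) parameters <- parameter_names(fit)
  d <- dim(fit$draws)
  out <- do.call(rbind, lapply(parameters, function(p) {
    data.frame(chain = rep(seq_len(d[1]), each = d[2]),
               iteration = rep(seq_len(d[2]), d[1]),
               parameter = p,
               value = as.vector(t(fit$draws[, , p])))
  }))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Monitored parameters for convergence gating
#'
#' The community hyper-means and the inclusion probability `omega`: the
#' quantities community-level inference is about. The community standard
#' deviations are weakly identified nuisance scales at typical design sizes
#' (tens of species); their diagnostics remain available through
#' [parameter_names()] with `hyper_only = TRUE`.
#'
#' @param fit an `rn_fit`.
#' @return character vector of parameter names.
#' @export
monitored_parameters <- function(fit) {
  nm <- dimnames(fit$draws)[[3]]
  nm[grepl("^(mu_|omega)", nm)]
}
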