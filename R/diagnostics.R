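# MCMC convergence diagnostics: split-chain potential scale reduction
# (Rhat) and autocorrelation-based effective sample size with Geyer's
# initial-monotone-sequence truncation.

#' Gelman-Rubin split-chain Rhat
#'
#' Each chain is split in half, and the potential scale reduction factor is
#' computed across the resulting sequences. Parameters with zero total
#' variance are reported as `Rhat = 1` with a `constant` flag.
#'
#' @param draws chains x iterations matrix, or an `rn_fit` (then Rhat is
#'   computed for every parameter, or those in `parameters`).
#' @param parameters optional parameter subset for the `rn_fit` method.
#' @return for a matrix, a list with `rhat` and `constant`; for an
#'   `rn_fit`, a named numeric vector of Rhat values with attribute
#'   `constant`.
#' @export
gelman_rubin <- function(draws, parameters = NULL) {
  if (inherits(draws, "rn_fit")) {
    if (is.null(parameters)) parameters <- parameter_names(draws)
    res <- vapply(parameters, function(p) {
      g <- gelman_rubin(extract_draws(draws, p, collapse = FALSE))
      c(g$rhat, g$constant)
    }, numeric(2))
    out <- res[1, ]
    attr(out, "constant") <- as.logical(res[2, ])
    return(out)
  }
  m <- as.matrix(draws)
  if (nrow(m) < 2) stop("need at least 2 chains")
  if (ncol(m) < 10) stop("need at least 10 retained draws per chain")
  half <- ncol(m) %/% 2
  seqs <- rbind(m[, seq_len(half), drop = FALSE],
                m[, half + seq_len(half), drop = FALSE])
  if (all(seqs == seqs[1, 1])) {
    return(list(rhat = 1, constant = TRUE))
  }
  n <- ncol(seqs)
  means <- rowMeans(seqs)
  vars <- apply(seqs, 1, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(list(rhat = 1, constant = TRUE))
  var_plus <- (n - 1) / n * W + B / n
  list(rhat = sqrt(var_plus / W), constant = FALSE)
}

#' Effective sample size
#'
#' Multi-chain autocorrelation-based ESS: per-lag autocorrelations are
#' combined across chains (between-chain variance inflates the estimate of
#' total variance as in split-Rhat), paired into Geyer sums, truncated at
#' the first negative pair, and forced monotone non-increasing. Constant
#' parameters get `NA` with a flag.
#'
#' @inheritParams gelman_rubin
#' @return for a matrix, a list with `ess` and `constant`; for an
#'   `rn_fit`, a named numeric vector with attribute `constant`.
#' @export
effective_sample_size <- function(draws, parameters = NULL) {
  if (inherits(draws, "rn_fit")) {
    if (is.null(parameters)) parameters <- parameter_names(draws)
    res <- vapply(parameters, function(p) {
      g <- effective_sample_size(extract_draws(draws, p, collapse = FALSE))
      c(if (is.na(g$ess)) NA_real_ else g$ess, g$constant)
    }, numeric(2))
    out <- res[1, ]
    attr(out, "constant") <- as.logical(res[2, ])
    return(out)
  }
  m <- as.matrix(draws)
  C <- nrow(m); n <- ncol(m)
  if (n < 10) stop("need at least 10 retained draws per chain")
  if (all(m == m[1, 1]) || all(apply(m, 1, var) == 0)) {
    return(list(ess = NA_real_, constant = TRUE))
  }
  chain_vars <- apply(m, 1, var)
  W <- mean(chain_vars)
  B_over_n <- if (C > 1) var(rowMeans(m)) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  # mean autocovariance at each lag across chains
  max_lag <- n - 2L
  acov <- matrix(0, C, max_lag + 1L)
  for (ch in seq_len(C)) {
    ac <- acf(m[ch, ], lag.max = max_lag, type = "covariance",
              plot = FALSE, demean = TRUE)$acf[, 1, 1]
    acov[ch, ] <- ac
  }
  mean_acov <- colMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer initial monotone positive sequence
  n_pairs <- (length(rho) - 1L) %/% 2L
  gamma_sum <- 0
  prev <- Inf
  for (p in seq_len(n_pairs)) {
    g <- rho[2 * p] + rho[2 * p + 1]
    if (g < 0) break
    g <- min(g, prev)
    gamma_sum <- gamma_sum + g
    prev <- g
  }
  tau <- max(1 + 2 * gamma_sum, 1 / (C * n)) # integrated autocorrelation time
  list(ess = C * n / tau, constant = FALSE)
}
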