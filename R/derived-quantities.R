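# Posterior summaries derived from retained Z and w draws: site-level
# species richness, aggregated relative abundance, and credible-interval
# effect-support classification.

# Flatten the chains x iterations dimensions of the Z array into one draw
# dimension: draws x species x sites.
pooled_Z <- function(fit) {
  d <- dim(fit$Z)
  Z <- aperm(fit$Z, c(2, 1, 3, 4))
  dim(Z) <- c(d[1] * d[2], d[3], d[4])
  Z
}

pooled_w <- function(fit) {
  wn <- paste0("w[", fit$data$species, "]")
  w <- fit$draws[, , wn, drop = FALSE]
  d <- dim(w)
  w <- aperm(w, c(2, 1, 3))
  dim(w) <- c(d[1] * d[2], d[3])
  w
}

#' Site-level posterior species richness
#'
#' Per retained draw, the richness of site `j` is the number of included
#' species with positive local abundance, `sum_i w_i * 1[Z_ij > 0]`;
#' posterior means and equal-tailed credible intervals are returned per
#' site.
#'
#' @param fit an `rn_fit` (must retain `Z` and `w` draws).
#' @param probs quantile pairs for the reported intervals.
#' @return `data.frame` with `site_id`, `mean`, and one column per quantile.
#' @export
site_richness <- function(fit, probs = c(0.05, 0.95)) {
  stopifnot(inherits(fit, "rn_fit"))
  if (is.null(fit$Z)) stop("fit does not retain Z draws")
  Z <- pooled_Z(fit); w <- pooled_w(fit)
  n_draw <- dim(Z)[1]; J <- dim(Z)[3]
  rich <- matrix(0, n_draw, J)
  for (j in seq_len(J)) {
    rich[, j] <- rowSums(w * (Z[, , j] > 0))
  }
  summarize_site_stat(rich, fit$data$sites, probs)
}

#' Site-level aggregated relative abundance
#'
#' Per retained draw, the total relative abundance of site `j` is
#' `sum_i w_i * Z_ij` (latent abundance summed over included species).
#' The posterior mean equals the sum over species of per-species posterior
#' mean abundance by linearity.
#'
#' @inheritParams site_richness
#' @return `data.frame` with `site_id`, `mean`, and one column per quantile.
#' @export
aggregated_relative_abundance <- function(fit, probs = c(0.05, 0.95)) {
  stopifnot(inherits(fit, "rn_fit"))
  if (is.null(fit$Z)) stop("fit does not retain Z draws")
  Z <- pooled_Z(fit); w <- pooled_w(fit)
  n_draw <- dim(Z)[1]; J <- dim(Z)[3]
  ab <- matrix(0, n_draw, J)
  for (j in seq_len(J)) {
    ab[, j] <- rowSums(w * Z[, , j])
  }
  summarize_site_stat(ab, fit$data$sites, probs)
}

summarize_site_stat <- function(stat, sites, probs) {
  qs <- apply(stat, 2, quantile, probs = probs)
  out <- data.frame(site_id = sites, mean = colMeans(stat))
  for (k in seq_along(probs)) {
    out[[sprintf("q%02.0f", probs[k] * 100)]] <- qs[k, ]
  }
  rownames(out) <- NULL
  out
}

#' Combined site summary table
#'
#' Posterior mean richness and aggregated relative abundance per site with
#' 90% equal-tailed intervals, joined to the covariate table; the input to
#' the post-hoc layer.
#'
#' @param fit an `rn_fit`.
#' @return `data.frame` with one row per site: `site_id`, `mean_richness`,
#'   `rich_lo90`, `rich_hi90`, `mean_abundance`, `abund_lo90`, `abund_hi90`
#'   plus covariate columns.
#' @export
site_summaries <- function(fit) {
  r <- site_richness(fit)
  a <- aggregated_relative_abundance(fit)
  out <- data.frame(site_id = r$site_id,
                    mean_richness = r$mean,
                    rich_lo90 = r$q05, rich_hi90 = r$q95,
                    mean_abundance = a$mean,
                    abund_lo90 = a$q05, abund_hi90 = a$q95)
  cv <- fit$covariates
  keep <- intersect(c("local_fire", "forest_type", "grassland", "burned_area",
                      "n_cameras"), names(cv))
  cbind(out, cv[match(out$site_id, cv$station_id), keep, drop = FALSE],
        row.names = NULL)
}

#' Classify the support for an effect from its posterior draws
#'
#' Equal-tailed 90% and 95% credible intervals: `strong` support if the 95%
#' interval excludes zero, else `moderate` if the 90% interval excludes
#' zero, else `weak`. Direction is the sign of the posterior mean.
#'
#' @param x numeric vector of posterior draws (>= 100).
#' @param label identifier for the summarised quantity.
#' @param parameter parameter name carried into the output.
#' @return one-row `data.frame`: `label`, `parameter`, `mean`, `lo90`,
#'   `hi90`, `lo95`, `hi95`, `support`, `direction`.
#' @export
classify_effect <- function(x, label = "effect", parameter = "") {
  stopifnot(is.numeric(x))
  if (length(x) < 100) stop("need at least 100 draws to classify an effect")
  ci90 <- quantile(x, c(0.05, 0.95), names = FALSE)
  ci95 <- quantile(x, c(0.025, 0.975), names = FALSE)
  support <- if (ci95[1] > 0 || ci95[2] < 0) "strong"
  else if (ci90[1] > 0 || ci90[2] < 0) "moderate"
  else "weak"
  data.frame(label = label, parameter = parameter, mean = mean(x),
             lo90 = ci90[1], hi90 = ci90[2],
             lo95 = ci95[1], hi95 = ci95[2],
             support = support,
             direction = if (mean(x) < 0) "negative" else "positive",
             stringsAsFactors = FALSE)
}

#' Assemblage-level effect: classification of a community mean
#'
#' [classify_effect()] applied to the posterior draws of a community
#' hyper-mean (e.g. `"mu_a5"`, the community response of abundance to the
#' forest-by-burned-area interaction).
#'
#' @param fit an `rn_fit`.
#' @param parameter community-mean parameter name.
#' @return one-row `data.frame` as in [classify_effect()].
#' @export
assemblage_effect <- function(fit, parameter = "mu_a5") {
  classify_effect(extract_draws(fit, parameter),
                  label = "assemblage", parameter = parameter)
}

#' Species-level effect table
#'
#' [classify_effect()] for a coefficient of every species (optionally only
#' observed ones), the per-species analogue of [assemblage_effect()].
#'
#' @param fit an `rn_fit`.
#' @param coefficient coefficient prefix, e.g. `"a5"`.
#' @param observed_only drop augmented species (default TRUE).
#' @return `data.frame`, one row per species.
#' @export
species_effects <- function(fit, coefficient = "a5", observed_only = TRUE) {
  sp <- fit$data$species
  if (observed_only) sp <- sp[!fit$data$augmented]
  do.call(rbind, lapply(sp, function(s) {
    classify_effect(extract_draws(fit, sprintf("%s[%s]", coefficient, s)),
                    label = s, parameter = coefficient)
  }))
}
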