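# Frequentist post-hoc layer on posterior site summaries: Shapiro-Wilk
# normality gate, Welch two-sample t-test, Wilcoxon rank-sum test, and
# per-forest-type linear regressions. The tests themselves delegate to
# stats::; this module contributes the gate logic and the tidy result
# schema.

#' Choose a two-sample test via a Shapiro-Wilk normality gate
#'
#' Welch's t-test is used only when Shapiro-Wilk does not reject normality
#' (p >= alpha) in both groups; otherwise the Wilcoxon rank-sum test. A
#' constant group has undefined normality and routes to Wilcoxon.
#'
#' @param x,y numeric samples (n >= 3 each).
#' @param alpha gate level (default 0.05).
#' @return `"welch"` or `"wilcoxon"`.
#' @export
choose_test <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) stop("need n >= 3 per group")
  p_of <- function(v) {
    if (sd(v) == 0) return(0) # constant: treat normality as rejected
    shapiro.test(v)$p.value
  }
  if (p_of(x) >= alpha && p_of(y) >= alpha) "welch" else "wilcoxon"
}

#' Welch two-sample t-test
#'
#' Two-sided Welch test (unequal variances, Welch-Satterthwaite df) via
#' [stats::t.test()], returned in the package's tidy two-sample schema.
#'
#' @param x,y numeric samples.
#' @return one-row `data.frame`: `test`, `statistic`, `df`, `p_value`,
#'   `estimate_x`, `estimate_y`, `n_x`, `n_y`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  if (sd(x) == 0 && sd(y) == 0) stop("both groups have zero variance")
  ht <- t.test(x, y, var.equal = FALSE)
  data.frame(test = "welch", statistic = unname(ht$statistic),
             df = unname(ht$parameter), p_value = ht$p.value,
             estimate_x = mean(x), estimate_y = mean(y),
             n_x = length(x), n_y = length(y), stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test via [stats::wilcox.test()]. The reported `W` is
#' R's convention: the rank sum of the first sample minus its minimum
#' (i.e. the Mann-Whitney U of the first sample). Exact p-values are used
#' for small tie-free samples, the tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y numeric samples.
#' @return one-row `data.frame` as in [welch_t()] (`df = NA`; estimates are
#'   group medians).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  ht <- suppressWarnings(wilcox.test(x, y))
  data.frame(test = "wilcoxon", statistic = unname(ht$statistic),
             df = NA_real_, p_value = ht$p.value,
             estimate_x = median(x), estimate_y = median(y),
             n_x = length(x), n_y = length(y), stringsAsFactors = FALSE)
}

#' Ordinary least-squares regression of a response on one predictor
#'
#' Wraps [stats::lm()]; reports the slope, intercept, R-squared and the
#' two-sided t-test p-value of the slope.
#'
#' @param x predictor (variance must be positive).
#' @param y response.
#' @return one-row `data.frame`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) < 3) stop("need n >= 3")
  if (var(x) == 0) stop("predictor has zero variance")
  fit <- lm(y ~ x)
  s <- summary(fit)
  data.frame(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             r_squared = s$r.squared,
             p_value = s$coefficients[2, 4], n = length(x))
}

#' Run the full post-hoc comparison battery
#'
#' Richness and aggregated relative abundance are each compared between
#' forest types and between burned/unburned sites (test chosen per
#' [choose_test()]), and regressed on burned-area proportion separately
#' within monospecific and polyspecific sites: four two-sample rows and
#' four regression rows.
#'
#' @param summaries site summary table from [site_summaries()] (or any
#'   `data.frame` with `mean_richness`, `mean_abundance`, `forest_type`,
#'   `local_fire`, `burned_area`).
#' @param alpha normality-gate level.
#' @return `data.frame`, one row per comparison: `comparison`, `response`,
#'   `stratum`, `test`, `statistic`, `df`, `p_value`, `n`, `note`.
#' @export
run_posthoc <- function(summaries, alpha = 0.05) {
  req <- c("mean_richness", "mean_abundance", "forest_type", "local_fire",
           "burned_area")
  if (!all(req %in% names(summaries))) {
    stop("summaries must have columns: ", paste(req, collapse = ", "))
  }
  rows <- list()
  two_sample <- function(resp, by, level_a, level_b, comparison) {
    x <- summaries[[resp]][summaries[[by]] == level_a]
    y <- summaries[[resp]][summaries[[by]] == level_b]
    if (length(x) < 3 || length(y) < 3) {
      return(data.frame(comparison = comparison, response = resp,
                        stratum = "all", test = NA_character_,
                        statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, n = length(x) + length(y),
                        note = "stratum with < 3 sites",
                        stringsAsFactors = FALSE))
    }
    res <- if (choose_test(x, y, alpha) == "welch") welch_t(x, y)
    else wilcoxon_rank_sum(x, y)
    data.frame(comparison = comparison, response = resp, stratum = "all",
               test = res$test, statistic = res$statistic, df = res$df,
               p_value = res$p_value, n = res$n_x + res$n_y, note = "",
               stringsAsFactors = FALSE)
  }
  regression <- function(resp, forest) {
    sub <- summaries[summaries$forest_type == forest, ]
    if (nrow(sub) < 3 || var(sub$burned_area) == 0) {
      return(data.frame(comparison = "burned_area_regression", response = resp,
                        stratum = forest, test = "ols", statistic = NA_real_,
                        df = NA_real_, p_value = NA_real_, n = nrow(sub),
                        note = "stratum with < 3 sites or constant predictor",
                        stringsAsFactors = FALSE))
    }
    res <- fit_linear(sub$burned_area, sub[[resp]])
    data.frame(comparison = "burned_area_regression", response = resp,
               stratum = forest, test = "ols", statistic = res$slope,
               df = res$n - 2, p_value = res$p_value, n = res$n,
               note = sprintf("r_squared=%.3f", res$r_squared),
               stringsAsFactors = FALSE)
  }
  for (resp in c("mean_richness", "mean_abundance")) {
    rows[[length(rows) + 1]] <-
      two_sample(resp, "forest_type", "monospecific", "polyspecific",
                 "forest_type")
    rows[[length(rows) + 1]] <-
      two_sample(resp, "local_fire", "burned", "unburned", "local_fire")
  }
  for (resp in c("mean_richness", "mean_abundance")) {
    for (forest in c("monospecific", "polyspecific")) {
      rows[[length(rows) + 1]] <- regression(resp, forest)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "w_convention") <-
    "wilcox.test: W = rank sum of first group minus n_x(n_x+1)/2"
  out
}
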