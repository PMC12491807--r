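#' Normality gate with log fallback
#'
#' Screens a sample with the Shapiro-Wilk test: if `p >= alpha` the
#' values pass through unchanged; otherwise a natural-log transform is
#' applied (the standard fallback for right-skewed imaging summary
#' statistics). Non-positive values force the documented shifted
#' transform `log(x + c)` with `c = 1 - min(x)`, and the shift is
#' recorded.
#'
#' @param values Numeric vector, `n >= 3` (Shapiro-Wilk requires
#'   3--5000).
#' @param alpha Gate level (default 0.05).
#'
#' @return A list: `values` (possibly transformed), `transform_applied`
#'   (`"none"` or `"log"`), `shift` (the constant `c`, 0 when unused),
#'   `shapiro_p` (p-value of the original sample).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    stop("normality screening requires n >= 3", call. = FALSE)
  if (length(values) > 5000L)
    values_test <- values[seq_len(5000L)] else values_test <- values
  p <- shapiro.test(values_test)$p.value
  if (p >= alpha)
    return(list(values = values, transform_applied = "none", shift = 0,
                shapiro_p = p))
  shift <- if (min(values) <= 0) 1 - min(values) else 0
  list(values = log(values + shift), transform_applied = "log",
       shift = shift, shapiro_p = p)
}

#' Fit the two-level treatment comparison mixed model
#'
#' Fits a linear mixed model with a fixed treatment effect and random
#' intercepts for animal and for unit nested in animal -- the minimal
#' random-effects structure accounting for repeated measures of the
#' same animals and the same pericytes/vessels across conditions. The
#' model is fit by maximum likelihood so the likelihood-ratio test
#' against the no-treatment null is valid; REML variance components are
#' reported alongside.
#'
#' @param table Data frame with columns `animal_id`, `unit_id`,
#'   `treatment` (two levels), and the response column. Every `unit_id`
#'   must nest within exactly one `animal_id`.
#' @param response Name of the response column (default `"value"`).
#' @param average_trials Average repeated trials within unit x
#'   treatment before fitting (default FALSE).
#'
#' @return A list of class `MixedModelResult`: `estimate` (treatment
#'   fixed effect), `se`, `ci` (95% Wald), `lrt_statistic`, `p_value`,
#'   `variance_components` (animal, unit, residual; ML),
#'   `variance_components_reml`, `singular` flag, `model_formula`,
#'   `n_obs`.
#' @export
fit_lmm <- function(table, response = "value", average_trials = FALSE) {
  stopifnot(all(c("animal_id", "unit_id", "treatment", response) %in%
                  names(table)))
  if (length(unique(table$animal_id)) < 2L)
    stop("need >= 2 animals", call. = FALSE)
  if (length(unique(table$treatment)) < 2L)
    stop("need both treatment levels", call. = FALSE)
  nest <- tapply(table$animal_id, table$unit_id,
                 function(a) length(unique(a)))
  if (any(nest > 1L))
    stop("unit_id values must nest within a single animal_id",
         call. = FALSE)
  df <- data.frame(animal_id = factor(table$animal_id),
                   unit_id = factor(table$unit_id),
                   treatment = factor(table$treatment,
                                      levels = unique(c("pre", "post",
                                                        as.character(table$treatment)))),
                   y = table[[response]])
  df$treatment <- droplevels(df$treatment)
  if (average_trials) {
    agg <- stats::aggregate(y ~ animal_id + unit_id + treatment, df, mean)
    df <- agg
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit_full <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ treatment + (1 | animal_id) + (1 | unit_id),
               data = df, REML = FALSE, control = ctrl)))
  fit_null <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | animal_id) + (1 | unit_id),
               data = df, REML = FALSE, control = ctrl)))
  ll_full <- as.numeric(stats::logLik(fit_full))
  ll_null <- as.numeric(stats::logLik(fit_null))
  lrt <- max(0, 2 * (ll_full - ll_null))
  p <- pchisq(lrt, df = 1L, lower.tail = FALSE)
  cf <- lme4::fixef(fit_full)
  est <- cf[[2L]]
  se <- tryCatch(
    suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit_full))))[2L]),
    error = function(e) NA_real_)
  if (!is.finite(se)) {
    # fall back to a refit with full derivative checks (rare: singular
    # fits under the fast control settings)
    refit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ treatment + (1 | animal_id) + (1 | unit_id),
                 data = df, REML = FALSE)))
    se <- suppressWarnings(sqrt(diag(as.matrix(stats::vcov(refit))))[2L])
  }
  vc <- as.data.frame(lme4::VarCorr(fit_full))
  getvar <- function(vc, g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1] else 0
  }
  fit_reml <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ treatment + (1 | animal_id) + (1 | unit_id),
               data = df, REML = TRUE, control = ctrl)))
  vcr <- as.data.frame(lme4::VarCorr(fit_reml))
  structure(list(
    estimate = est, se = se,
    ci = est + c(-1, 1) * stats::qnorm(0.975) * se,
    lrt_statistic = lrt, p_value = p,
    variance_components = c(animal = getvar(vc, "animal_id"),
                            unit = getvar(vc, "unit_id"),
                            residual = getvar(vc, "Residual")),
    variance_components_reml = c(animal = getvar(vcr, "animal_id"),
                                 unit = getvar(vcr, "unit_id"),
                                 residual = getvar(vcr, "Residual")),
    singular = lme4::isSingular(fit_full),
    model_formula = "y ~ treatment + (1 | animal) + (1 | unit:animal)",
    n_obs = nrow(df)),
    class = "MixedModelResult")
}

#' @export
print.MixedModelResult <- function(x, ...) {
  cat(sprintf(
    "<MixedModelResult> estimate %.4g [%.4g, %.4g], LRT %.3g, p = %.3g%s\n",
    x$estimate, x$ci[1], x$ci[2], x$lrt_statistic, x$p_value,
    if (x$singular) " (singular fit)" else ""))
  invisible(x)
}

#' Holm-sequential (step-down Bonferroni) adjustment
#'
#' Adjusted p-values by the Holm step-down rule: with the raw values
#' sorted ascending, `adj_(i) = max_{j <= i} min(1, (m - j + 1) p_(j))`,
#' returned in the original order. The adjustment is monotone in the
#' sorted order, never decreases a p-value, and is idempotent.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#'
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj_sorted <- cummax(pmin((m - seq_len(m) + 1) * p[o], 1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}
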