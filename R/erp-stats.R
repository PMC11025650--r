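#' Assemble a single-trial analysis table
#'
#' Joins an ERP table (one row per subject x word token, with N400 amplitude
#' and pre-word baseline) with model-based predictors. Because the N400 is a
#' negative deflection, the Semantic Update column is multiplied by -1 before
#' modeling. Predictors (including the baseline) are z-scored by default so
#' that fixed-effect magnitudes are comparable across predictors; the scaling
#' constants are recorded in the `"metadata"` attribute. ERP rows whose
#' `word_id` has no predictor value are dropped, with the count logged.
#'
#' @param erp data frame with columns `subject`, `word_id`, `n400`,
#'   `baseline`.
#' @param predictors data frame with columns `word_id`, `su`, `surprisal` and
#'   optionally `internal_lm`.
#' @param standardize z-score predictor columns (default `TRUE`).
#' @param negate_su multiply SU by -1 (default `TRUE`).
#' @return Trial table (data frame) with attribute `"metadata"` recording the
#'   options, scaling constants and number of dropped rows.
#' @export
assemble_trials <- function(erp, predictors, standardize = TRUE,
                            negate_su = TRUE) {
  need <- c("subject", "word_id", "n400", "baseline")
  if (!all(need %in% names(erp)))
    stop2("`erp` needs columns ", paste(need, collapse = ", "))
  if (!all(c("word_id", "su", "surprisal") %in% names(predictors)))
    stop2("`predictors` needs columns word_id, su, surprisal")
  m <- match(erp$word_id, predictors$word_id)
  dropped <- sum(is.na(m))
  if (dropped > 0)
    message(dropped, " ERP row(s) without matching predictors dropped")
  keep <- !is.na(m)
  if (!any(keep)) stop2("zero ERP rows matched the predictor table")
  d <- erp[keep, need, drop = FALSE]
  m <- m[keep]
  d$su <- predictors$su[m]
  d$surprisal <- predictors$surprisal[m]
  if ("internal_lm" %in% names(predictors))
    d$internal_lm <- predictors$internal_lm[m]
  if (negate_su) d$su <- -d$su
  pred_cols <- intersect(c("baseline", "su", "surprisal", "internal_lm"),
                         names(d))
  scale_info <- NULL
  if (standardize) {
    scale_info <- lapply(d[pred_cols], function(x)
      c(mean = mean(x), sd = stats::sd(x)))
    d[pred_cols] <- lapply(d[pred_cols], z_score)
  }
  rownames(d) <- NULL
  attr(d, "metadata") <- list(standardize = standardize,
                              negate_su = negate_su, dropped = dropped,
                              scale = scale_info)
  d
}

mixed_formula <- function(response, baseline, fixed, random_slopes) {
  slope_part <- if (length(random_slopes) > 0)
    paste("(1 +", paste(random_slopes, collapse = " + "), "| subject)")
  else "(1 | subject)"
  stats::as.formula(paste(
    response, "~", paste(c(baseline, fixed), collapse = " + "), "+",
    slope_part, "+ (1 | word_id)"))
}

extract_fit <- function(m, fixed, random_slopes, fallback) {
  sm <- tryCatch(stats::coef(summary(m)), error = function(e) NULL)
  if (is.null(sm) || ncol(sm) < 5L) {
    # Satterthwaite unavailable: normal-approximation p-values on the t ratio
    if (is.null(sm)) sm <- stats::coef(summary(lme4::refitML(m)))
    tvals <- sm[, ncol(sm)]
    sm <- cbind(sm[, 1:2, drop = FALSE], df = NA_real_, t = tvals,
                p = 2 * stats::pnorm(-abs(tvals)))
  }
  coefs <- data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
                      df = sm[, 3], t = sm[, 4], p = sm[, 5],
                      row.names = NULL)
  ll <- stats::logLik(m)
  msgs <- m@optinfo$conv$lme4$messages
  structure(list(
    coefficients = coefs,
    logLik = as.numeric(ll),
    n_par = attr(ll, "df"),
    AIC = stats::AIC(m),
    nobs = stats::nobs(m),
    converged = is.null(msgs) ||
      !any(grepl("failed to converge", msgs, ignore.case = TRUE)),
    singular = lme4::isSingular(m),
    fallback = fallback,
    varcor = as.data.frame(lme4::VarCorr(m)),
    sigma = stats::sigma(m),
    fixed = fixed, random_slopes = random_slopes,
    formula = deparse1(stats::formula(m))),
    class = "mixed_model_result")
}

#' Fit the baseline-covaried mixed-effects N400 model
#'
#' Fits `n400 ~ baseline + <predictors> + (1 + <slopes> | subject) +
#' (1 | word_id)` by maximum likelihood (not REML, so that nested
#' likelihood-ratio comparisons over fixed effects are valid). The baseline
#' enters as a covariate of no interest and carries no random slope; random
#' slopes by subject are fitted for the predictors of interest given in
#' `random_slopes`. Per-coefficient p-values use Satterthwaite degrees of
#' freedom, with a normal approximation as fallback. On a convergence
#' failure, a fallback ladder (drop random slopes, then random intercepts
#' only) is applied and recorded in the result.
#'
#' @param trials a trial table from [assemble_trials()] (any data frame with
#'   `subject`, `word_id`, the response and predictor columns works).
#' @param fixed character vector of predictor-of-interest column names.
#' @param random_slopes subset of `fixed` receiving by-subject random slopes.
#' @param response,baseline column names of the response and the baseline
#'   covariate (set `baseline = NULL` to omit it).
#' @param fallback apply the convergence fallback ladder (default `TRUE`).
#'   Set to `FALSE` to always keep the requested random structure (the fit is
#'   flagged instead), e.g. when nested models must stay comparable.
#' @return An object of class `mixed_model_result` with elements
#'   `coefficients` (`term`, `beta`, `se`, `df`, `t`, `p`), `logLik`, `n_par`,
#'   `AIC`, `nobs`, `converged`, `singular`, `fallback`, `varcor` and `sigma`.
#' @export
fit_mixed_model <- function(trials, fixed = c("su", "surprisal"),
                            random_slopes = fixed, response = "n400",
                            baseline = "baseline", fallback = TRUE) {
  if (length(unique(trials$subject)) < 2L) stop2("need >= 2 subjects")
  if (length(unique(trials$word_id)) < 2L) stop2("need >= 2 words")
  for (col in c(baseline, fixed)) {
    if (!col %in% names(trials)) stop2("missing predictor column: ", col)
    if (stats::sd(trials[[col]]) == 0)
      stop2("predictor is constant across trials: ", col)
  }
  for (col in setdiff(random_slopes, fixed)) {
    # a slope without the fixed effect is legitimate when comparing nested
    # models that must share their random structure
    if (!col %in% names(trials)) stop2("missing random-slope column: ", col)
  }
  ladders <- if (fallback) unique(list(random_slopes, character(0)))
             else list(random_slopes)
  fit <- NULL
  for (i in seq_along(ladders)) {
    fml <- mixed_formula(response, baseline, fixed, ladders[[i]])
    m <- tryCatch(
      suppressMessages(lmerTest::lmer(fml, data = trials, REML = FALSE)),
      error = function(e) NULL)
    if (is.null(m)) next
    fit <- extract_fit(m, fixed, ladders[[i]],
                       fallback = if (i == 1L) "none" else "dropped slopes")
    if (fit$converged) break
  }
  if (is.null(fit)) stop2("mixed model could not be fitted")
  fit
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("<mixed_model_result> ", x$formula, "\n", sep = "")
  cat(sprintf("  ML fit, logLik %.2f, AIC %.2f, n = %d%s\n", x$logLik, x$AIC,
              x$nobs,
              if (!x$converged) " (NOT converged)" else
                if (x$fallback != "none") paste0(" (", x$fallback, ")") else ""))
  print(cbind(x$coefficients[, c("term", "beta", "se", "t")],
              p = signif(x$coefficients$p, 3)), row.names = FALSE)
  invisible(x)
}

#' Wald confidence intervals for the fixed effects
#'
#' @param fit a `mixed_model_result`.
#' @param level confidence level.
#' @return Data frame `term`, `lower`, `upper` (t quantile on the
#'   Satterthwaite df where available, normal otherwise).
#' @export
fixed_ci <- function(fit, level = 0.95) {
  co <- fit$coefficients
  q <- ifelse(is.finite(co$df) & co$df > 0,
              stats::qt(1 - (1 - level) / 2, co$df),
              stats::qnorm(1 - (1 - level) / 2))
  data.frame(term = co$term, lower = co$beta - q * co$se,
             upper = co$beta + q * co$se)
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' For two maximum-likelihood fits on identical rows with `m0` nested in
#' `m1`: `chisq = 2 (logLik1 - logLik0)` (clipped at zero), `df` the
#' parameter-count difference, the p-value from the upper tail of the
#' chi-squared distribution, and `delta_aic = AIC0 - AIC1` (positive values
#' favor the larger model).
#'
#' @param m0,m1 `mixed_model_result` objects (`m0` nested in `m1`).
#' @return List of class `model_comparison` with `chisq`, `df`, `p`,
#'   `delta_aic`.
#' @export
compare_models <- function(m0, m1) {
  if (m0$nobs != m1$nobs)
    stop2("models were fitted on different numbers of rows")
  nested <- all(m0$fixed %in% m1$fixed) &&
    all(m0$random_slopes %in% m1$random_slopes) && m0$n_par <= m1$n_par
  if (!nested) stop2("`m0` is not nested in `m1`")
  chisq <- max(0, 2 * (m1$logLik - m0$logLik))
  df <- m1$n_par - m0$n_par
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else
    as.numeric(chisq == 0)
  structure(list(chisq = chisq, df = df, p = p,
                 delta_aic = m0$AIC - m1$AIC),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> chisq(%d) = %.3f, p = %.3g, deltaAIC = %.1f\n",
              x$df, x$chisq, x$p, x$delta_aic))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a vector of p-values; the rejection mask is monotone
#' in the raw p-values.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return List with `p_adjusted` and logical `reject` (both empty for empty
#'   input).
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  if (length(p) == 0L)
    return(list(p_adjusted = numeric(0), reject = logical(0)))
  if (any(!is.na(p) & (p < 0 | p > 1))) stop2("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}
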