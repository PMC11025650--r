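test_that("trial assembly negates SU, standardizes and logs dropped rows", {
  pred <- data.frame(word_id = c("w1", "w2", "w3"),
                     su = c(0.3, 0.5, 0.1), surprisal = c(1, 2, 3))
  erp <- expand.grid(subject = c("S1", "S2"),
                     word_id = c("w1", "w2", "w3", "w9"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  erp$n400 <- rnorm(8)
  erp$baseline <- rnorm(8)

  expect_message(tr <- assemble_trials(erp, pred, standardize = FALSE),
                 "dropped")
  expect_equal(nrow(tr), 6L)
  expect_equal(tr$su[tr$word_id == "w1"][1], -0.3)  # negated, raw scale
  expect_equal(attr(tr, "metadata")$dropped, 2L)

  trz <- suppressMessages(assemble_trials(erp, pred))
  for (col in c("baseline", "su", "surprisal")) {
    expect_equal(mean(trz[[col]]), 0, tolerance = 1e-9)
    expect_equal(sd(trz[[col]]), 1, tolerance = 1e-9)
  }
  expect_error(assemble_trials(erp[erp$word_id == "w9", ], pred), "zero")
})

test_that("noise-free trials recover the planted coefficients exactly", {
  pred <- simulated_predictors(40L, seed = 15L)
  spec <- erp_spec(n_subjects = 6L, sd_subject = 0, sd_slope_su = 0,
                   sd_word = 0, sd_resid = 0, intercept = 0.25)
  d <- generate_erp_trials(spec, pred, seed = 1L)
  tr <- assemble_trials(d, pred, standardize = FALSE)
  fit <- suppressWarnings(
    fit_mixed_model(tr, fixed = c("su", "surprisal"),
                    random_slopes = character(0)))
  beta <- fit$coefficients$beta
  names(beta) <- fit$coefficients$term
  expect_equal(unname(beta["(Intercept)"]), 0.25, tolerance = 1e-6)
  expect_equal(unname(beta["baseline"]), -0.4, tolerance = 1e-6)
  expect_equal(unname(beta["su"]), 0.2, tolerance = 1e-6)
  expect_equal(unname(beta["surprisal"]), 0.15, tolerance = 1e-6)
})

test_that("mixed-model fits expose a valid AIC/logLik identity and guards", {
  pred <- simulated_predictors(30L, seed = 16L)
  d <- generate_erp_trials(erp_spec(n_subjects = 5L), pred, seed = 3L)
  tr <- assemble_trials(d, pred, standardize = FALSE)
  fit <- suppressWarnings(fit_mixed_model(tr, fixed = "su",
                                          random_slopes = "su"))
  expect_equal(fit$AIC, 2 * fit$n_par - 2 * fit$logLik, tolerance = 1e-8)
  expect_true(all(fit$coefficients$p >= 0 & fit$coefficients$p <= 1))

  tr$flat <- 1
  expect_error(fit_mixed_model(tr, fixed = "flat"), "constant.*flat")
  one_subj <- tr[tr$subject == tr$subject[1], ]
  expect_error(fit_mixed_model(one_subj, fixed = "su"), "subjects")
})

test_that("model comparison arithmetic and nesting guards hold", {
  mk <- function(ll, k, nobs, fixed, slopes = character(0)) {
    structure(list(logLik = ll, n_par = k, AIC = 2 * k - 2 * ll, nobs = nobs,
                   fixed = fixed, random_slopes = slopes),
              class = "mixed_model_result")
  }
  # equal log-likelihoods, one extra parameter: chisq 0, p 1, deltaAIC -2
  cmp <- compare_models(mk(-100, 5, 200, "a"), mk(-100, 6, 200, c("a", "b")))
  expect_equal(cmp$chisq, 0)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$delta_aic, -2)

  expect_error(compare_models(mk(-10, 5, 100, "a"), mk(-9, 6, 200, c("a", "b"))),
               "different numbers of rows")
  expect_error(compare_models(mk(-10, 5, 100, c("a", "c")),
                              mk(-9, 6, 100, c("a", "b"))),
               "not nested")

  # a real nested pair: chisq equals twice the logLik gap, clipped at zero
  pred <- simulated_predictors(40L, seed = 17L)
  d <- generate_erp_trials(erp_spec(n_subjects = 6L), pred, seed = 5L)
  tr <- assemble_trials(d, pred, standardize = FALSE)
  f1 <- suppressWarnings(fit_mixed_model(tr, fixed = c("su", "surprisal"),
                                         random_slopes = character(0)))
  f0 <- suppressWarnings(fit_mixed_model(tr, fixed = "surprisal",
                                         random_slopes = character(0)))
  cmp <- compare_models(f0, f1)
  expect_equal(cmp$df, 1L)
  expect_equal(cmp$chisq, max(0, 2 * (f1$logLik - f0$logLik)))
  expect_equal(cmp$p, pchisq(cmp$chisq, 1, lower.tail = FALSE))
})

test_that("BH correction matches the exhaustive step-up oracle", {
  # worked example: p = (.01, .02, .03, .04) at alpha = .05 -> all rejected
  # (oracle: largest k with p_(k) <= .05 k/4 is k = 4)
  out <- fdr_correct(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(out$reject))
  expect_true(fdr_correct(0.04, 0.05)$reject)       # m = 1: raw threshold
  expect_false(any(fdr_correct(rep(0.5, 6), 0.05)$reject))
  expect_length(fdr_correct(numeric(0))$reject, 0L)
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(23)
  for (i in 1:1000) {
    n <- sample(1:25, 1)
    p <- round(runif(n), 3)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    out <- fdr_correct(p, alpha)
    expect_identical(out$reject, bh_step_up_oracle(p, alpha))
    # monotonicity of the mask in the raw p-values
    if (any(out$reject)) expect_lte(max(p[out$reject]),
                                    min(c(p[!out$reject], Inf)))
  }
})
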