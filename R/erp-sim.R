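#' Specification of the single-trial ERP generator
#'
#' Generative twin of the N400 mixed-effects regression: single-trial N400
#' amplitudes are produced from a linear mixed model with fixed effects for
#' the pre-word baseline, (negated) Semantic Update and surprisal, crossed
#' by-subject and by-word random effects, and Gaussian residual noise. Because
#' the N400 is a negativity, the SU predictor enters the generator multiplied
#' by -1, mirroring the sign convention of the analysis stage.
#'
#' Default effect sizes echo the scale of published single-trial N400
#' regressions (baseline -0.4, SU 0.2, surprisal 0.15, in standardized units);
#' variance components default to a subject-intercept SD of 0.5, an SU
#' random-slope SD of 0.1, a word-intercept SD of 0.3 and residual SD 1.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param beta_baseline,beta_su,beta_surprisal,intercept fixed effects.
#' @param sd_subject by-subject random-intercept SD.
#' @param sd_slope_su by-subject random-slope SD for (negated) SU.
#' @param sd_slope_surprisal by-subject random-slope SD for surprisal.
#' @param sd_word by-word random-intercept SD.
#' @param sd_resid residual SD.
#' @param sd_baseline SD of the i.i.d. Gaussian baseline values.
#' @return A list of class `erp_spec`.
#' @export
erp_spec <- function(n_subjects = 12L, beta_baseline = -0.4, beta_su = 0.2,
                     beta_surprisal = 0.15, intercept = 0,
                     sd_subject = 0.5, sd_slope_su = 0.1,
                     sd_slope_surprisal = 0, sd_word = 0.3, sd_resid = 1,
                     sd_baseline = 1) {
  spec <- list(n_subjects = as.integer(n_subjects),
               beta_baseline = beta_baseline, beta_su = beta_su,
               beta_surprisal = beta_surprisal, intercept = intercept,
               sd_subject = sd_subject, sd_slope_su = sd_slope_su,
               sd_slope_surprisal = sd_slope_surprisal, sd_word = sd_word,
               sd_resid = sd_resid, sd_baseline = sd_baseline)
  sds <- unlist(spec[grep("^sd_", names(spec))])
  if (any(sds < 0)) stop2("all SDs must be >= 0")
  if (spec$n_subjects < 2L) stop2("need at least 2 subjects")
  class(spec) <- "erp_spec"
  spec
}

#' Generate single-trial N400 amplitudes with planted effects
#'
#' One row per (subject, word token). The generating model is
#' `N400 = intercept + b_base * baseline + b_su * (-SU) + b_surp * surprisal
#' + u_subject + s_subject * (-SU) + s2_subject * surprisal + w_word + eps`
#' (the surprisal slope SD is zero by default).
#' All latent draws (random effects and residuals) are recorded in the
#' `"latents"` attribute for inspection, so fitted models can be checked
#' against the exact generating quantities.
#'
#' @param spec an [erp_spec()].
#' @param predictors data frame with columns `word_id` (unique), `su` and
#'   `surprisal` (finite). The raw, positive SU is supplied; negation happens
#'   inside the generator.
#' @param seed RNG seed.
#' @return Data frame with columns `subject`, `word_id`, `baseline`, `su`,
#'   `surprisal`, `n400` (`n_subjects * n_words` rows) and attribute
#'   `"latents"`.
#' @export
generate_erp_trials <- function(spec, predictors, seed = 1L) {
  stopifnot(inherits(spec, "erp_spec"))
  need <- c("word_id", "su", "surprisal")
  if (!all(need %in% names(predictors)))
    stop2("`predictors` needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(predictors$word_id)) stop2("`word_id` must be unique")
  if (!all(is.finite(predictors$su)) || !all(is.finite(predictors$surprisal)))
    stop2("predictor values must be finite")
  n_words <- nrow(predictors)
  if (n_words < 2L) stop2("need at least 2 words")
  ns <- spec$n_subjects
  with_seed(seed, {
    u_subj <- stats::rnorm(ns, 0, spec$sd_subject)
    s_su <- stats::rnorm(ns, 0, spec$sd_slope_su)
    s_surp <- stats::rnorm(ns, 0, spec$sd_slope_surprisal)
    w_word <- stats::rnorm(n_words, 0, spec$sd_word)
    d <- data.frame(
      subject = rep(sprintf("S%02d", seq_len(ns)), each = n_words),
      word_id = rep(predictors$word_id, ns),
      su = rep(predictors$su, ns),
      surprisal = rep(predictors$surprisal, ns))
    d$baseline <- stats::rnorm(nrow(d), 0, spec$sd_baseline)
    eps <- stats::rnorm(nrow(d), 0, spec$sd_resid)
    si <- rep(seq_len(ns), each = n_words)
    wi <- rep(seq_len(n_words), ns)
    d$n400 <- spec$intercept + spec$beta_baseline * d$baseline +
      spec$beta_su * (-d$su) + spec$beta_surprisal * d$surprisal +
      u_subj[si] + s_su[si] * (-d$su) + s_surp[si] * d$surprisal +
      w_word[wi] + eps
    attr(d, "latents") <- list(u_subject = u_subj, s_su = s_su,
                               s_surprisal = s_surp, w_word = w_word,
                               residual = eps)
    d
  })
}

#' Triangular effect-curve constructor
#'
#' A piecewise-linear "tent" rising from `onset` to a peak and back to
#' `offset`; symmetric tents have their 50% fractional-area latency exactly at
#' the peak.
#'
#' @param onset,peak,offset milliseconds.
#' @param amplitude peak height.
#' @return Function of time (vectorized).
#' @export
effect_curve_triangle <- function(onset = 250, peak = 400, offset = 550,
                                  amplitude = 1) {
  force(onset); force(peak); force(offset); force(amplitude)
  function(t) {
    up <- (t - onset) / (peak - onset)
    down <- (offset - t) / (offset - peak)
    amplitude * pmax(0, pmin(up, down))
  }
}

#' Specification of the EEG time-course generator
#'
#' @param times sampling grid in ms (strictly increasing).
#' @param effect function of time giving the effect curve `beta(t)` that
#'   multiplies the predictor of interest.
#' @param electrodes electrode names.
#' @param gains per-electrode multiplicative gains (finite).
#' @param n_subjects number of subjects.
#' @param noise_sd residual noise SD.
#' @param sd_subject by-subject intercept SD.
#' @param sd_word by-word intercept SD.
#' @param beta_baseline effect of the per-trial baseline value (constant over
#'   time).
#' @return A list of class `timecourse_spec`.
#' @export
timecourse_spec <- function(times = seq(0, 650, by = 25),
                            effect = effect_curve_triangle(),
                            electrodes = c("Cz", "Pz", "CP1", "CP2"),
                            gains = rep(1, length(electrodes)),
                            n_subjects = 8L, noise_sd = 0.5,
                            sd_subject = 0.3, sd_word = 0.2,
                            beta_baseline = -0.4) {
  if (length(times) == 0L) stop2("empty sampling grid")
  if (any(diff(times) <= 0)) stop2("`times` must be strictly increasing")
  if (!all(is.finite(gains)) || length(gains) != length(electrodes))
    stop2("`gains` must be finite, one per electrode")
  structure(list(times = times, effect = effect, electrodes = electrodes,
                 gains = gains, n_subjects = as.integer(n_subjects),
                 noise_sd = noise_sd, sd_subject = sd_subject,
                 sd_word = sd_word, beta_baseline = beta_baseline),
            class = "timecourse_spec")
}

#' Generate a long-format EEG time-course table with a planted effect
#'
#' Produces `amplitude(subject, word, electrode, t) = gain_e * beta(t) * x_w +
#' b_base * baseline + u_subject + w_word + noise`, where `x_w` is the
#' per-word predictor of interest. The true fractional-area latency of the
#' effect curve (rectified, 50% fraction, computed on a 1 ms grid) is returned
#' alongside the data.
#'
#' @param spec a [timecourse_spec()].
#' @param predictors data frame with columns `word_id` and `x` (predictor of
#'   interest, e.g. negated SU).
#' @param seed RNG seed.
#' @return List with `eeg` (long data frame: subject, word_id, electrode,
#'   time, amplitude), `trials` (per subject x word: baseline and `x`) and
#'   `true_latency` (ms).
#' @export
generate_timecourse <- function(spec, predictors, seed = 1L) {
  stopifnot(inherits(spec, "timecourse_spec"))
  if (!all(c("word_id", "x") %in% names(predictors)))
    stop2("`predictors` needs columns word_id, x")
  nw <- nrow(predictors)
  ns <- spec$n_subjects
  ne <- length(spec$electrodes)
  nt <- length(spec$times)
  with_seed(seed, {
    u_subj <- stats::rnorm(ns, 0, spec$sd_subject)
    w_word <- stats::rnorm(nw, 0, spec$sd_word)
    trials <- expand.grid(subject = sprintf("S%02d", seq_len(ns)),
                          word_id = predictors$word_id,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    trials$x <- predictors$x[match(trials$word_id, predictors$word_id)]
    trials$baseline <- stats::rnorm(nrow(trials))
    beta_t <- spec$effect(spec$times)
    grid <- expand.grid(time = spec$times, electrode = spec$electrodes,
                        row = seq_len(nrow(trials)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tr <- trials[grid$row, ]
    gain <- spec$gains[match(grid$electrode, spec$electrodes)]
    amp <- gain * beta_t[match(grid$time, spec$times)] * tr$x +
      spec$beta_baseline * tr$baseline +
      u_subj[match(tr$subject, sprintf("S%02d", seq_len(ns)))] +
      w_word[match(tr$word_id, predictors$word_id)] +
      stats::rnorm(nrow(grid), 0, spec$noise_sd)
    eeg <- data.frame(subject = tr$subject, word_id = tr$word_id,
                      electrode = grid$electrode, time = grid$time,
                      amplitude = amp, stringsAsFactors = FALSE)
    fine <- seq(min(spec$times), max(spec$times), by = 1)
    true_lat <- tryCatch(fractional_area_latency(fine, spec$effect(fine)),
                         error = function(e) NA_real_)  # flat curve
    list(eeg = eeg, trials = trials, true_latency = true_lat)
  })
}
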