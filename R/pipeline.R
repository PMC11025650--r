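#' Score stimulus sentences with both models
#'
#' Runs the SG update network and the language model over every stimulus
#' sentence and returns one row per (sentence, position, token) with Semantic
#' Update, surprisal and the LM-internal update. The correlation between the
#' SU and surprisal columns is computed and stored in the `"metadata"`
#' attribute (reported, not asserted: it depends on the training data).
#'
#' @param sg_model a trained `sg_model`.
#' @param lm_model a trained `lm_model`.
#' @param stimuli list of [frame_sentence()] objects or character token
#'   vectors.
#' @return Data frame with columns `word_id`, `sentence_id`, `position`,
#'   `token`, `su`, `surprisal`, `internal_lm`.
#' @export
score_stimuli <- function(sg_model, lm_model, stimuli) {
  su_tab <- sg_score_corpus(sg_model, stimuli)
  lm_tab <- lm_score_corpus(lm_model, stimuli)
  d <- merge(su_tab, lm_tab, by = c("sentence_id", "position", "token"))
  d <- d[order(d$sentence_id, d$position), ]
  d <- data.frame(word_id = sprintf("s%03d_w%02d", d$sentence_id, d$position),
                  d, row.names = NULL)
  attr(d, "metadata") <- list(
    n_sentences = length(stimuli),
    su_surprisal_correlation = stats::cor(d$su, d$surprisal))
  d
}

#' Demo run configuration
#'
#' Bundles the seeds, scale preset and analysis options that govern
#' [run_demo()]. All randomness flows from the named seeds; two runs with the
#' same configuration on the same platform produce identical outputs.
#'
#' @param out_dir output directory (created if missing); `NULL` for no file
#'   output.
#' @param seeds named list of integer seeds: `corpus`, `sg`, `lm`, `erp`,
#'   `timecourse`.
#' @param preset `"desk"` (small sizes) or `"paper"` (full-scale sizes).
#' @param n_sentences training-corpus size.
#' @param n_stimuli number of stimulus sentences scored and analysed.
#' @param world a [micro_world()].
#' @param sg,lm,erp optional [sg_config()], [lm_config()], [erp_spec()]
#'   overriding the preset-derived defaults.
#' @param standardize z-score predictors in the trial table.
#' @param random_slopes predictors carrying by-subject random slopes in the
#'   N400 models.
#' @param tc_times sampling grid (ms) of the synthetic EEG time course.
#' @param tc_noise_sd noise SD of the synthetic EEG time course.
#' @param latency_fraction fractional-area fraction.
#' @return List of class `run_config`.
#' @export
demo_config <- function(out_dir = NULL,
                        seeds = list(corpus = 11L, sg = 21L, lm = 31L,
                                     erp = 41L, timecourse = 51L),
                        preset = c("desk", "paper"),
                        n_sentences = 400L, n_stimuli = 40L,
                        world = micro_world(),
                        sg = NULL, lm = NULL, erp = NULL,
                        standardize = TRUE,
                        random_slopes = c("su", "surprisal"),
                        tc_times = seq(0, 650, by = 25),
                        tc_noise_sd = 0.4,
                        latency_fraction = 0.5) {
  preset <- match.arg(preset)
  cfg <- list(out_dir = out_dir, seeds = seeds, preset = preset,
              n_sentences = as.integer(n_sentences),
              n_stimuli = as.integer(n_stimuli), world = world,
              sg = sg %||% sg_config(preset, seed = seeds$sg),
              lm = lm %||% lm_config(preset, seed = seeds$lm),
              erp = erp %||% erp_spec(),
              standardize = standardize, random_slopes = random_slopes,
              tc_times = tc_times, tc_noise_sd = tc_noise_sd,
              latency_fraction = latency_fraction)
  class(cfg) <- "run_config"
  cfg
}

#' Read a demo configuration from a YAML file
#'
#' Scalar fields of the YAML file override the [demo_config()] defaults;
#' recognised keys are `out_dir`, `seeds`, `preset`, `n_sentences`,
#' `n_stimuli`, `standardize`, `random_slopes`, `tc_noise_sd`,
#' `latency_fraction`.
#'
#' @param path path to a YAML file.
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop2("the `yaml` package is required to read YAML configurations")
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("out_dir", "seeds", "preset", "n_sentences",
                          "n_stimuli", "standardize", "random_slopes",
                          "tc_noise_sd", "latency_fraction"))]
  do.call(demo_config, args)
}

coef_table <- function(fit) {
  fit$coefficients[, c("term", "beta", "t", "p")]
}

comparison_row <- function(label, cmp) {
  list(models = label, chisq = cmp$chisq, df = cmp$df, p = cmp$p,
       delta_aic = cmp$delta_aic)
}

# per-subject effect-curve latencies from ordinary per-time-point least
# squares (no subject-level random terms, mirroring per-subject analysis)
per_subject_latencies <- function(eeg, trials, predictor, window,
                                  fraction = 0.5) {
  subjects <- sort(unique(eeg$subject))
  times <- sort(unique(eeg$time))
  times <- times[times >= window[1] & times <= window[2]]
  vapply(subjects, function(s) {
    betas <- vapply(times, function(tt) {
      d <- eeg[eeg$subject == s & eeg$time == tt,
               c("word_id", "amplitude")]
      d <- merge(d, trials[trials$subject == s, ], by = "word_id")
      fml <- stats::as.formula(paste("amplitude ~ baseline +", predictor))
      stats::coef(stats::lm(fml, data = d))[[predictor]]
    }, 0)
    tryCatch(fractional_area_latency(times, betas, fraction),
             error = function(e) NA_real_)
  }, 0)
}

#' Run the end-to-end demonstration pipeline
#'
#' Executes the full analysis chain on synthetic data: sample a micro-world
#' corpus, train the SG model and the language model, score a held-out
#' stimulus set (SU, surprisal, internal update), generate single-trial N400
#' amplitudes whose planted effects are driven by the scored predictors, fit
#' and compare the baseline-covaried mixed models, and run the time-course,
#' topography and fractional-area latency analyses on a synthetic EEG time
#' course. Writes a machine-readable report (JSON) plus CSV tables when
#' `out_dir` is set; fully reproducible from the configured seeds.
#'
#' @param config a [demo_config()].
#' @return The report, invisibly: a nested list with elements `n400_tables`
#'   (per-model coefficient tables), `comparisons` (chi-squared / delta-AIC
#'   rows), `predictors` (summary including the SU-surprisal correlation),
#'   `timecourse` (per-predictor significant spans and latencies) and
#'   `manifest`.
#' @export
run_demo <- function(config = demo_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    message(sprintf("[%s] ...", name))
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop2("stage '", name, "' failed: ", conditionMessage(e)))
    message(sprintf("[%s] done (%.1f s)", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  corpus <- stage("simulate-corpus",
                  sample_corpus(config$world, config$n_sentences,
                                seed = config$seeds$corpus))
  stimuli <- stage("simulate-stimuli",
                   sample_corpus(config$world, config$n_stimuli,
                                 seed = config$seeds$corpus + 7919L))
  sg <- stage("train-sg", train_sg(corpus, config$sg))
  lm <- stage("train-lm", train_lm(corpus, config$lm))
  predictors <- stage("score", score_stimuli(sg, lm, stimuli))

  # the generator's planted fixed effects are stated in standardized units,
  # so the scored predictors are z-scored across stimulus words before
  # planting
  pred_std <- predictors
  pred_std$su <- z_score(predictors$su)
  pred_std$surprisal <- z_score(predictors$surprisal)
  erp <- stage("simulate-erp",
               generate_erp_trials(config$erp, pred_std,
                                   seed = config$seeds$erp))
  trials <- assemble_trials(erp, pred_std,
                            standardize = config$standardize)
  fits <- stage("analyze-n400", {
    list(su = fit_mixed_model(trials, fixed = "su",
                              random_slopes = intersect("su", config$random_slopes)),
         surprisal = fit_mixed_model(trials, fixed = "surprisal",
                                     random_slopes = intersect("surprisal", config$random_slopes)),
         both = fit_mixed_model(trials, fixed = c("su", "surprisal"),
                                random_slopes = intersect(c("su", "surprisal"),
                                                          config$random_slopes)))
  })
  comparisons <- list(
    comparison_row("surprisal vs surprisal + su",
                   compare_models(fits$surprisal, fits$both)),
    comparison_row("su vs su + surprisal",
                   compare_models(fits$su, fits$both)))

  tc <- stage("analyze-timecourse", {
    # planted effect curves: the semantic effect peaks later and lasts
    # longer than the lexical one, matching the hypothesis the demo probes
    curves <- list(su = effect_curve_triangle(250, 450, 600, 0.6),
                   surprisal = effect_curve_triangle(250, 375, 500, 0.6))
    xs <- list(su = -pred_std$su, surprisal = pred_std$surprisal)
    out <- list()
    for (nm in names(curves)) {
      spec_tc <- timecourse_spec(times = config$tc_times,
                                 effect = curves[[nm]],
                                 n_subjects = config$erp$n_subjects,
                                 noise_sd = config$tc_noise_sd)
      gen <- generate_timecourse(
        spec_tc, data.frame(word_id = predictors$word_id, x = xs[[nm]]),
        seed = config$seeds$timecourse + match(nm, names(curves)))
      roi <- roi_average(gen$eeg, spec_tc$electrodes)
      tr <- gen$trials
      names(tr)[names(tr) == "x"] <- nm
      tpw <- fit_timepointwise(roi, tr, predictor = nm,
                               window = range(config$tc_times))
      lat <- fractional_area_latency(tpw$table$time, tpw$table$beta,
                                     config$latency_fraction)
      psl <- per_subject_latencies(roi, tr, nm, range(config$tc_times),
                                   config$latency_fraction)
      out[[nm]] <- list(timepointwise = tpw, latency = lat,
                        subject_latencies = psl,
                        true_latency = gen$true_latency,
                        topography = if (nm == "su")
                          fit_topography(gen$eeg, tr, predictor = nm) else NULL)
    }
    out$latency_test <- per_subject_latency_test(
      out$su$subject_latencies, out$surprisal$subject_latencies)
    out
  })

  report <- list(
    n400_tables = lapply(fits, coef_table),
    comparisons = comparisons,
    predictors = list(
      n_stimulus_words = nrow(predictors),
      su_surprisal_correlation =
        attr(predictors, "metadata")$su_surprisal_correlation),
    timecourse = list(
      su = list(latency_ms = tc$su$latency,
                true_latency_ms = tc$su$true_latency,
                n_significant = sum(tc$su$timepointwise$table$reject)),
      surprisal = list(latency_ms = tc$surprisal$latency,
                       true_latency_ms = tc$surprisal$true_latency,
                       n_significant =
                         sum(tc$surprisal$timepointwise$table$reject)),
      latency_test = tc$latency_test),
    manifest = list(seeds = config$seeds, preset = config$preset,
                    n_sentences = config$n_sentences,
                    n_stimuli = config$n_stimuli,
                    standardize = config$standardize,
                    package_version =
                      as.character(utils::packageVersion("gestaltN400")),
                    r_version = paste(R.version$major, R.version$minor,
                                      sep = ".")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_frame_corpus(corpus, file.path(config$out_dir, "corpus.jsonl"))
    utils::write.csv(predictors, file.path(config$out_dir, "predictors.csv"),
                     row.names = FALSE)
    utils::write.csv(erp, file.path(config$out_dir, "erp_trials.csv"),
                     row.names = FALSE)
    utils::write.csv(tc$su$timepointwise$table,
                     file.path(config$out_dir, "timecourse_su.csv"),
                     row.names = FALSE)
    utils::write.csv(tc$surprisal$timepointwise$table,
                     file.path(config$out_dir, "timecourse_surprisal.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
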