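#' Average an EEG table over a region of interest
#'
#' Collapses a long-format EEG table over a set of electrodes into a single
#' virtual electrode by taking, for every (subject, word, time), the mean
#' amplitude across the set.
#'
#' @param eeg long-format data frame with columns `subject`, `word_id`,
#'   `electrode`, `time`, `amplitude`.
#' @param electrodes character vector of electrode names (non-empty, all
#'   present in the table).
#' @param name name given to the virtual electrode.
#' @return Long-format data frame with one `electrode` level.
#' @export
roi_average <- function(eeg, electrodes, name = "ROI") {
  if (length(electrodes) == 0L) stop2("empty electrode set")
  missing_e <- setdiff(electrodes, unique(eeg$electrode))
  if (length(missing_e) > 0)
    stop2("electrodes not present: ", paste(missing_e, collapse = ", "))
  d <- eeg[eeg$electrode %in% electrodes, ]
  agg <- stats::aggregate(amplitude ~ subject + word_id + time, data = d,
                          FUN = mean)
  agg$electrode <- name
  agg[, c("subject", "word_id", "electrode", "time", "amplitude")]
}

# fit the standard trial-level model for one response vector; returns the
# row of `predictor`'s coefficient or NULL on failure
timepoint_fit <- function(d, predictor, random_slopes) {
  fit <- tryCatch(
    fit_mixed_model(d, fixed = predictor, random_slopes = random_slopes),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- fit$coefficients[fit$coefficients$term == predictor, ]
  if (nrow(co) != 1L) return(NULL)
  co
}

#' Time-point-wise mixed-effects regression of the EEG signal
#'
#' Fits, at every sampling point of the grid inside `window`, the same
#' baseline-covaried mixed model as [fit_mixed_model()] with the given
#' predictor of interest, then applies Benjamini-Hochberg correction across
#' all time points of the analysis (one FDR family per analysis). Time points
#' whose model cannot be fitted are flagged, get `NA` coefficients and are
#' excluded from the FDR family.
#'
#' @param eeg long-format EEG table (typically ROI-averaged, one electrode).
#' @param trials data frame with one row per (subject, word): `subject`,
#'   `word_id`, `baseline` and the predictor column named in `predictor`.
#' @param predictor name of the predictor-of-interest column in `trials`.
#' @param window analysis window in ms, `c(start, end)`.
#' @param random_slopes predictors receiving by-subject random slopes
#'   (default none, keeping the per-time-point models light).
#' @param alpha FDR level for the rejection mask.
#' @return Object of class `timecourse_result`: data frame `table` with
#'   columns `time`, `beta`, `se`, `t`, `p`, `reject`, `failed`, plus fields
#'   `predictor`, `window`, `alpha`.
#' @export
fit_timepointwise <- function(eeg, trials, predictor = "su",
                              window = c(0, 650), random_slopes = character(0),
                              alpha = 0.05) {
  times <- sort(unique(eeg$time))
  times <- times[times >= window[1] & times <= window[2]]
  if (length(times) == 0L) stop2("no sampling points inside `window`")
  rows <- lapply(times, function(tt) {
    d <- eeg[eeg$time == tt, c("subject", "word_id", "amplitude")]
    names(d)[3] <- "n400"
    d <- merge(d, trials, by = c("subject", "word_id"))
    co <- timepoint_fit(d, predictor, random_slopes)
    if (is.null(co))
      data.frame(time = tt, beta = NA_real_, se = NA_real_, t = NA_real_,
                 p = NA_real_, failed = TRUE)
    else
      data.frame(time = tt, beta = co$beta, se = co$se, t = co$t, p = co$p,
                 failed = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$failed
  tab$reject <- FALSE
  if (any(ok)) tab$reject[ok] <- fdr_correct(tab$p[ok], alpha)$reject
  if (any(tab$failed))
    message(sum(tab$failed), " time point(s) failed to fit; excluded from FDR")
  structure(list(table = tab, predictor = predictor, window = window,
                 alpha = alpha),
            class = "timecourse_result")
}

#' @export
print.timecourse_result <- function(x, ...) {
  cat(sprintf(paste0("<timecourse_result> %s over %d time points (%g-%g ms);",
                     " %d significant at FDR %.2f\n"),
              x$predictor, nrow(x$table), x$window[1], x$window[2],
              sum(x$table$reject), x$alpha))
  invisible(x)
}

#' Topographic window-wise regression
#'
#' Averages the amplitude within non-overlapping time windows of
#' `window_width` ms, fits one baseline-covaried mixed model per
#' (electrode, window) cell, and applies Benjamini-Hochberg correction across
#' all cells of the analysis. A remainder of the analysis span that does not
#' fill a whole window is truncated with a warning.
#'
#' @inheritParams fit_timepointwise
#' @param window_width window width in ms (default 50).
#' @param span analysis span in ms, `c(start, end)`.
#' @return Object of class `topography_result`: data frame `table` with
#'   columns `electrode`, `win_start`, `win_end`, `beta`, `se`, `t`, `p`,
#'   `reject`, `failed`.
#' @export
fit_topography <- function(eeg, trials, predictor = "su", window_width = 50,
                           span = c(0, 600), random_slopes = character(0),
                           alpha = 0.05) {
  electrodes <- unique(eeg$electrode)
  if (length(electrodes) == 0L) stop2("no electrodes in table")
  n_win <- floor((span[2] - span[1]) / window_width)
  if (n_win < 1L) stop2("`span` shorter than one window")
  if (span[1] + n_win * window_width < span[2])
    warning("analysis span is not a multiple of the window width; ",
            "remainder truncated", call. = FALSE)
  starts <- span[1] + (seq_len(n_win) - 1L) * window_width
  cells <- expand.grid(electrode = electrodes, win_start = starts,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    e <- cells$electrode[i]; w0 <- cells$win_start[i]
    w1 <- w0 + window_width
    d <- eeg[eeg$electrode == e & eeg$time >= w0 & eeg$time < w1, ]
    base <- data.frame(electrode = e, win_start = w0, win_end = w1)
    if (nrow(d) == 0L)
      return(cbind(base, beta = NA_real_, se = NA_real_, t = NA_real_,
                   p = NA_real_, failed = TRUE))
    d <- stats::aggregate(amplitude ~ subject + word_id, data = d, FUN = mean)
    names(d)[3] <- "n400"
    d <- merge(d, trials, by = c("subject", "word_id"))
    co <- timepoint_fit(d, predictor, random_slopes)
    if (is.null(co))
      cbind(base, beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
            failed = TRUE)
    else
      cbind(base, beta = co$beta, se = co$se, t = co$t, p = co$p,
            failed = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$failed
  tab$reject <- FALSE
  if (any(ok)) tab$reject[ok] <- fdr_correct(tab$p[ok], alpha)$reject
  structure(list(table = tab, predictor = predictor,
                 window_width = window_width, span = span, alpha = alpha),
            class = "topography_result")
}

#' @export
print.topography_result <- function(x, ...) {
  cat(sprintf(paste0("<topography_result> %s: %d electrode x window cells ",
                     "(%g ms windows over %g-%g ms); %d significant at ",
                     "FDR %.2f\n"),
              x$predictor, nrow(x$table), x$window_width, x$span[1],
              x$span[2], sum(x$table$reject), x$alpha))
  invisible(x)
}

#' Fractional-area latency of an effect curve
#'
#' The smallest time point at which the cumulative area under the (by default
#' rectified) curve reaches `fraction` of its total area over the analysis
#' window. The cumulative area is computed by trapezoidal integration on the
#' grid, with linear interpolation between grid points to locate the
#' crossing.
#'
#' @param times sampling grid in ms.
#' @param beta effect-curve values on the grid.
#' @param fraction area fraction (default 0.5).
#' @param window analysis window `c(start, end)` (defaults to the grid range).
#' @param rectify integrate `|beta|` (default) rather than the signed curve.
#' @return Latency in ms.
#' @export
fractional_area_latency <- function(times, beta, fraction = 0.5,
                                    window = range(times), rectify = TRUE) {
  keep <- times >= window[1] & times <= window[2] & is.finite(beta)
  t <- times[keep]; y <- beta[keep]
  if (length(t) < 2L) stop2("need at least 2 finite points inside `window`")
  if (rectify) y <- abs(y)
  ca <- cum_trapz(t, y)
  total <- ca[length(ca)]
  if (total <= 0) stop2("zero total area: latency undefined")
  target <- fraction * total
  i <- which(ca >= target)[1L]
  if (i == 1L) return(t[1L])
  # linear interpolation of the cumulative-area curve between grid points
  t[i - 1L] + (target - ca[i - 1L]) / (ca[i] - ca[i - 1L]) * (t[i] - t[i - 1L])
}

#' Paired t test on per-subject effect latencies
#'
#' Compares per-subject fractional-area latencies of two predictors with a
#' two-sided paired t test. Subjects with an undefined latency for either
#' predictor are excluded and logged.
#'
#' @param latency_a,latency_b numeric vectors of per-subject latencies (ms),
#'   aligned by subject.
#' @return List with `mean_a`, `mean_b`, `mean_diff`, `t`, `df`, `p`,
#'   `n_used`, `n_excluded`.
#' @export
per_subject_latency_test <- function(latency_a, latency_b) {
  if (length(latency_a) != length(latency_b))
    stop2("latency vectors must be aligned by subject")
  ok <- is.finite(latency_a) & is.finite(latency_b)
  if (sum(ok) < 2L) stop2("need >= 2 subjects with defined latencies")
  if (any(!ok))
    message(sum(!ok), " subject(s) with undefined latency excluded")
  a <- latency_a[ok]; b <- latency_b[ok]
  d <- a - b
  if (stats::sd(d) == 0) {
    # degenerate: constant difference, no variance to test against
    return(list(mean_a = mean(a), mean_b = mean(b), mean_diff = mean(d),
                t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(a) - 1L, p = as.numeric(mean(d) == 0),
                n_used = length(a), n_excluded = sum(!ok)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(mean_a = mean(a), mean_b = mean(b), mean_diff = mean(a - b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_used = length(a), n_excluded = sum(!ok))
}
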