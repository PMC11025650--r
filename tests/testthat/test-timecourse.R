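test_that("ROI averaging equals the group-by mean", {
  eeg <- data.frame(subject = "S1", word_id = "w1",
                    electrode = c("Cz", "Pz"), time = 100,
                    amplitude = c(1, 3))
  roi <- roi_average(eeg, c("Cz", "Pz"))
  expect_equal(roi$amplitude, 2)

  # singleton set is the identity on amplitudes
  one <- roi_average(eeg, "Cz")
  expect_equal(one$amplitude, 1)

  set.seed(24)
  big <- expand.grid(subject = c("S1", "S2"), word_id = c("w1", "w2", "w3"),
                     electrode = c("a", "b", "c"), time = c(0, 50),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  big$amplitude <- rnorm(nrow(big))
  roi <- roi_average(big, c("a", "c"))
  oracle <- tapply(big$amplitude[big$electrode %in% c("a", "c")],
                   with(big[big$electrode %in% c("a", "c"), ],
                        paste(subject, word_id, time)), mean)
  expect_equal(as.numeric(oracle[paste(roi$subject, roi$word_id, roi$time)]),
               roi$amplitude)
  expect_error(roi_average(big, character(0)), "empty")
  expect_error(roi_average(big, "zz"), "not present")
})

test_that("fractional-area latency matches closed forms and a fine-grid oracle", {
  t <- seq(200, 600, by = 10)
  tri <- effect_curve_triangle(200, 400, 600, 2)
  expect_equal(fractional_area_latency(t, tri(t)), 400)

  # constant curve: latency at the window midpoint
  expect_equal(fractional_area_latency(seq(0, 600, 50), rep(1.5, 13)), 300)

  # piecewise-linear curves vs. dense cumulative-trapezoid oracle
  set.seed(25)
  for (i in 1:20) {
    knots_t <- seq(0, 650, length.out = 14)
    knots_y <- pmax(0, rnorm(14, 1, 0.8))
    knots_y[c(1, 14)] <- 0
    grid <- seq(0, 650, by = 5)
    y <- approx(knots_t, knots_y, xout = grid)$y
    fine <- seq(0, 650, by = 0.01)
    yf <- approx(knots_t, knots_y, xout = fine)$y
    ca <- cumsum(c(0, diff(fine) * (yf[-1] + yf[-length(yf)]) / 2))
    oracle <- fine[which(ca >= 0.5 * ca[length(ca)])[1]]
    expect_lt(abs(fractional_area_latency(grid, y) - oracle), 1)
  }
})

test_that("fractional-area latency is monotone, scale-free and reflects", {
  set.seed(26)
  t <- seq(0, 650, by = 10)
  y <- abs(rnorm(length(t))) + 0.1
  l25 <- fractional_area_latency(t, y, fraction = 0.25)
  l50 <- fractional_area_latency(t, y, fraction = 0.5)
  l75 <- fractional_area_latency(t, y, fraction = 0.75)
  expect_true(l25 <= l50 && l50 <= l75)
  expect_equal(fractional_area_latency(t, 10 * y), l50)
  # reflecting the curve about the window midpoint reflects the latency
  refl <- fractional_area_latency(t, rev(y))
  expect_equal(refl, max(t) + min(t) - l50, tolerance = 1e-9)
  expect_equal(fractional_area_latency(t, -y), l50)  # rectification
  expect_error(fractional_area_latency(t, rep(0, length(t))), "zero total")
})

test_that("time-point-wise fits localize a noise-free boxcar effect", {
  set.seed(27)
  nw <- 24L
  pred <- data.frame(word_id = sprintf("w%02d", seq_len(nw)),
                     x = as.numeric(scale(rnorm(nw))))
  boxcar <- function(t) as.numeric(t >= 300 & t <= 500) * 0.8
  spec <- timecourse_spec(times = seq(0, 650, by = 50), effect = boxcar,
                          electrodes = "ROI", gains = 1, n_subjects = 5L,
                          noise_sd = 0, sd_subject = 0, sd_word = 0,
                          beta_baseline = -0.4)
  gen <- generate_timecourse(spec, pred, seed = 4L)
  tr <- gen$trials
  names(tr)[names(tr) == "x"] <- "su"
  res <- suppressWarnings(suppressMessages(
    fit_timepointwise(gen$eeg, tr, predictor = "su", window = c(0, 650))))
  tab <- res$table
  expect_equal(nrow(tab), 14L)  # grid points in window
  inside <- tab$time >= 300 & tab$time <= 500
  expect_equal(tab$beta[inside], rep(0.8, sum(inside)), tolerance = 1e-6)
  expect_equal(tab$beta[!inside], rep(0, sum(!inside)), tolerance = 1e-6)
})

test_that("topography windows partition the span and localize effects", {
  set.seed(28)
  nw <- 20L
  pred <- data.frame(word_id = sprintf("w%02d", seq_len(nw)),
                     x = as.numeric(scale(rnorm(nw))))
  boxcar <- function(t) as.numeric(t >= 300 & t < 500) * 1
  # a sliver of noise keeps the residual variance positive so the per-cell
  # p-values are well defined; the planted effect is overwhelming
  spec <- timecourse_spec(times = seq(0, 595, by = 5), effect = boxcar,
                          electrodes = c("Cz", "F1"), gains = c(1, 0),
                          n_subjects = 5L, noise_sd = 0.05, sd_subject = 0,
                          sd_word = 0, beta_baseline = -0.4)
  gen <- generate_timecourse(spec, pred, seed = 5L)
  tr <- gen$trials
  names(tr)[names(tr) == "x"] <- "su"
  res <- suppressWarnings(suppressMessages(
    fit_topography(gen$eeg, tr, predictor = "su", window_width = 50,
                   span = c(0, 600))))
  tab <- res$table
  expect_equal(nrow(tab), 24L)  # 12 windows x 2 electrodes
  expect_equal(sort(unique(tab$win_start)), seq(0, 550, by = 50))
  # gain-zero electrode never significant; effect windows on Cz all are
  hot <- tab$electrode == "Cz" & tab$win_start >= 300 & tab$win_start < 500
  expect_true(all(tab$reject[hot]))
  expect_equal(tab$beta[hot], rep(1, sum(hot)), tolerance = 0.05)
  expect_false(any(tab$reject[tab$electrode == "F1"]))
  expect_error(fit_topography(gen$eeg[0, ], tr), "electrodes|window")
})

test_that("paired latency test matches the closed-form paired t", {
  expect_equal(per_subject_latency_test(rep(400, 6), rep(400, 6))$t, 0)
  expect_equal(per_subject_latency_test(rep(400, 6), rep(400, 6))$p, 1)

  # planted 100 ms shift, noise-free
  a <- seq(480, 500, length.out = 12)
  out <- per_subject_latency_test(a, a - 100)
  expect_equal(out$mean_diff, 100)
  expect_lt(out$p, 0.001)

  set.seed(29)
  x <- rnorm(10, 400, 30); y <- rnorm(10, 380, 30)
  out <- per_subject_latency_test(x, y)
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(out$t, t_oracle, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(t_oracle), length(d) - 1), tolerance = 1e-12)

  # undefined latencies are excluded
  expect_message(out2 <- per_subject_latency_test(c(x, NA), c(y, 400)),
                 "excluded")
  expect_equal(out2$n_used, 10L)
})
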