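test_that("reference fit recovers the channel relationship", {
  tr <- photometry_trace(0:2, c(2, 4, 6), c(1, 2, 3))
  fit <- fit_reference(tr)
  expect_equal(unname(fit), c(2, 0), tolerance = 1e-12)

  tr_id <- photometry_trace(0:4, 1:5, 1:5)
  expect_equal(unname(fit_reference(tr_id)), c(1, 0), tolerance = 1e-12)

  # noisy regression agrees with the lm oracle
  set.seed(17)
  f410 <- 100 + cumsum(rnorm(500))
  f470 <- 1.5 * f410 + 0.2 + rnorm(500, 0, 0.3)
  tr_n <- photometry_trace(seq_along(f410), f470, f410)
  fit_n <- fit_reference(tr_n)
  ref <- unname(coef(lm(f470 ~ f410)))
  expect_equal(unname(fit_n[c("intercept", "slope")]), ref,
               tolerance = 1e-9)
  expect_equal(unname(fit_n["slope"]), 1.5, tolerance = 0.05)

  const <- photometry_trace(0:4, 1:5, rep(2, 5))
  expect_error(fit_reference(const), "constant 410")
})

test_that("dF/F vanishes for identical channels and isolates transients", {
  shape <- 50 + 10 * sin(seq(0, 10, 0.05))
  tr <- photometry_trace(seq(0, 10, 0.05), shape, shape)
  d <- compute_dff(tr)
  expect_equal(max(abs(d$dff)), 0, tolerance = 1e-12)

  # additive transient on f470 with flat-plus-tilt reference:
  # dff peak = amplitude / fitted baseline
  # long recording so the brief transient barely influences the fit
  t <- seq(0, 2000, 0.05)
  f410 <- 100 + 0.01 * t                  # slight trend keeps regression defined
  bump <- transient_kernel(t - 500, amplitude = 8, tau_rise_s = 0.5,
                           tau_decay_s = 2)
  tr2 <- photometry_trace(t, 2 * f410 + bump, f410)
  d2 <- compute_dff(tr2)
  peak_factor <- max(bump)
  # whole-recording fit absorbs a sliver of the transient: sub-percent match
  expect_equal(max(d2$dff), peak_factor / (2 * f410[which.max(bump)]),
               tolerance = 5e-3)
})

test_that("shared multiplicative motion artifact is suppressed", {
  sim <- simulate_photometry(duration_s = 300, motion_amp = 0.05,
                             noise_sd = 0, events = numeric(0), seed = 1)
  d <- compute_dff(sim$trace)
  raw_var <- var(sim$trace$f470 / mean(sim$trace$f470) - 1)
  expect_lt(var(d$dff), 0.05 * raw_var)
})

test_that("peri-event extraction uses a shared grid and drops edge events", {
  sim <- simulate_photometry(duration_s = 120, events = 60, seed = 3)
  d <- compute_dff(sim$trace)
  pem <- extract_peri_event(d, 60, feeding_window())
  expect_equal(ncol(pem$mat), 30 * 20 + 1)  # 601 samples at 20 Hz
  expect_equal(nrow(pem$mat), 1)
  expect_equal(pem$rel_t[1], -20)
  expect_equal(pem$rel_t[length(pem$rel_t)], 10)

  # an event 5 s after start cannot host a window starting at -20 s
  pem2 <- extract_peri_event(d, c(5, 60), feeding_window())
  expect_equal(nrow(pem2$mat), 1)
  expect_equal(pem2$n_dropped, 1)
  expect_error(extract_peri_event(d, 5, feeding_window()), "no events")

  pem3 <- extract_peri_event(d, c(50, 60), transition_window())
  expect_equal(pem3$rel_t, pem$rel_t[pem$rel_t >= -10])
})

test_that("AUC is a trapezoidal integral with closed-form agreement", {
  w <- analysis_window(-20, 10)
  rel_t <- seq(-20, 10, 0.05)
  expect_equal(auc(rep(0.2, length(rel_t)), rel_t, w), 30 * 0.2)
  expect_equal(auc(rep(0, length(rel_t)), rel_t, w), 0)

  # double-exponential kernel over (0, 10) at 20 Hz vs closed form
  grid <- seq(0, 10, 0.05)
  y <- exp(-grid / 2) - exp(-grid / 0.5)
  closed <- 2 * (1 - exp(-5)) - 0.5 * (1 - exp(-20))
  got <- auc(y, grid, analysis_window(0, 10))
  expect_lt(abs(got - closed) / closed, 0.02)

  # linearity on a shared grid
  set.seed(4)
  x <- rnorm(length(rel_t)); yv <- rnorm(length(rel_t))
  expect_equal(auc(2 * x + 3 * yv, rel_t, w),
               2 * auc(x, rel_t, w) + 3 * auc(yv, rel_t, w),
               tolerance = 1e-9)

  expect_error(auc(y, grid, analysis_window(-5, 10)), "beyond")
})

test_that("peak dF/F is the signed maximum in percent", {
  rel_t <- seq(-10, 10, 0.05)
  expect_equal(peak_dff(rep(0.03, length(rel_t)), rel_t,
                        analysis_window(-10, 10)), 3)
  neg <- rep(-0.02, length(rel_t))
  expect_equal(peak_dff(neg, rel_t, analysis_window(-10, 10)), -2)

  # kernel peak within one sample of the analytic maximum
  grid <- seq(0, 10, 0.05)
  y <- exp(-grid / 2) - exp(-grid / 0.5)
  t_star <- log(4) / 1.5
  analytic <- 100 * (exp(-t_star / 2) - exp(-t_star / 0.5))
  got <- peak_dff(y, grid, analysis_window(0, 10))
  near <- 100 * y[abs(grid - t_star) <= 0.05]
  expect_true(abs(got - analytic) <= max(abs(near - analytic)) + 1e-12)
})

test_that("peri-event averaging reports mean, sem, AUC and peak per event", {
  rel_t <- seq(-10, 10, 0.5)
  w <- analysis_window(-10, 10)
  mk <- function(mat) structure(list(rel_t = rel_t, mat = mat,
                                     event_times = seq_len(nrow(mat)),
                                     window = w, n_dropped = 0L),
                                class = "peri_event_matrix")
  one <- mk(matrix(sin(rel_t), 1))
  s1 <- peri_event_average(one)
  expect_equal(s1$mean, sin(rel_t))
  expect_equal(s1$sem, rep(0, length(rel_t)))

  v <- cos(rel_t)
  s2 <- peri_event_average(mk(rbind(v, -v)))
  expect_equal(s2$mean, rep(0, length(rel_t)), ignore_attr = TRUE)

  s3 <- peri_event_average(mk(rbind(v, v, v)))
  expect_equal(s3$sem, rep(0, length(rel_t)), ignore_attr = TRUE)
  expect_length(s3$auc, 3)
  expect_length(s3$peak_pct, 3)
  expect_equal(s3$peak_pct, rep(100, 3), ignore_attr = TRUE)
})

test_that("photometry CSV round-trips the trace", {
  path <- withr::local_tempfile(fileext = ".csv")
  sim <- simulate_photometry(duration_s = 10, seed = 6)
  write_photometry(sim$trace, path)
  back <- read_photometry(path)
  expect_identical(back$t_s, sim$trace$t_s)
  expect_identical(back$f470, sim$trace$f470)
  expect_identical(back$f410, sim$trace$f410)
  expect_equal(back$rate_hz, sim$trace$rate_hz)
})
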