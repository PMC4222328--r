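sine_recording <- function(freq, dur = 20, rate = 1000, amp = 1) {
  t <- seq(1 / rate, dur, by = 1 / rate)
  make_recording(matrix(amp * sin(2 * pi * freq * t), 1), rate)
}

test_that("band-pass is unit-gain mid-band, kills DC, and is zero-phase", {
  f <- bandpass_filter(sine_recording(10))
  mid <- 5000:15000
  gain <- max(abs(f$signal[1, mid]))
  expect_gte(gain, 0.95)
  expect_lte(gain, 1.05)

  dc <- make_recording(matrix(100, 1, 20000), 1000)
  fdc <- bandpass_filter(dc)
  expect_lt(sqrt(mean(fdc$signal[1, mid]^2)), 100 / 10^(20 / 20))  # >= 20 dB

  imp <- make_recording(matrix(c(rep(0, 4999), 1, rep(0, 5000)), 1), 1000)
  fi <- bandpass_filter(imp, filter_length = 2001)
  expect_equal(which.max(fi$signal[1, ]), 5000L)  # no group delay

  expect_error(bandpass_filter(sine_recording(10), lo = 30, hi = 10),
               "config error")
  expect_error(bandpass_filter(sine_recording(10), hi = 600),
               "config error")
})

test_that("decimation rescales length and event indices exactly", {
  rate <- 1000
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)       # sample 1 at t = 0
  rec <- make_recording(matrix(sin(2 * pi * 10 * t), 1), rate,
                        events = data.frame(sample = 1001L, label = "s",
                                            is_deviant = FALSE,
                                            is_habituation = FALSE,
                                            is_post_deviant = FALSE))
  r <- resample(rec, 200)
  expect_equal(ncol(r$signal), 2000L)             # exactly 1/5 of the length
  expect_equal(r$events$sample, 201L)             # sample offset 1000 -> 200
  expect_equal(r$rate, 200)
  # decimated samples sit on the t = k/200 grid
  ref <- sin(2 * pi * 10 * seq(0, 10 - 1 / 200, by = 1 / 200))
  expect_gt(cor(r$signal[1, 100:1900], ref[100:1900]), 0.999)

  expect_identical(resample(rec, 1000), rec)      # identity at target = rate
  expect_error(resample(rec, 2000), "config error")
  expect_error(resample(rec, 300), "must divide")
})

test_that("EOG derivation follows the subtraction recipe", {
  sig <- rbind(3, 1, 1)
  rec <- make_recording(matrix(sig, 3, 5), roles = rep("EOG", 3))
  rec$channel_names <- c("EOGup", "EOGlow", "EOGlat")
  rec$roles <- c("EOG", "EOG", "EEG")  # montage needs an EEG channel? not here
  out <- derive_eog(rec)
  expect_equal(out$signal[match("vEOG", out$channel_names), ], rep(2, 5))
  expect_equal(out$signal[match("hEOG", out$channel_names), ], rep(1, 5))

  rec2 <- make_recording(rbind(rnorm(5), rnorm(5), rnorm(5)))
  rec2$channel_names <- c("EOGup", "EOGlow", "EOGlat")
  rec2$signal[2, ] <- rec2$signal[1, ]            # upper == lower
  expect_equal(derive_eog(rec2)$signal[4, ], rep(0, 5))
  expect_error(derive_eog(make_recording(matrix(0, 1, 5))), "missing channel")
})

test_that("component screening applies the strict correlation threshold", {
  set.seed(11)
  n <- 400
  veog <- rnorm(n)
  heog <- rnorm(n)
  ortho <- residuals(lm(rnorm(n) ~ veog + heog))
  tc <- rbind(veog, ortho, rnorm(n))
  flagged <- screen_components(tc, veog, heog)
  expect_true(1 %in% flagged)                     # r = 1 with vEOG
  expect_false(2 %in% flagged)                    # orthogonal to both
  # component whose |r| equals the threshold exactly is NOT flagged
  r2 <- abs(cor(tc[3, ], veog))
  expect_false(3 %in% screen_components(tc[3, , drop = FALSE], veog, heog,
                                        r_thresh = r2))
  expect_true(3 %in% seq_len(3))
  expect_warning(screen_components(rbind(rep(1, n)), veog, heog),
                 "zero variance")
})

test_that("component removal reconstructs known mixtures", {
  set.seed(21)
  n <- 500
  t1 <- sin(2 * pi * 7 * seq_len(n) / n) * 5     # dominant component
  t2 <- residuals(lm(rnorm(n) ~ t1))
  t1 <- t1 - mean(t1); t2 <- t2 - mean(t2)
  m1 <- c(1, 0, 0, 0) * 3; m2 <- c(0, 1, 0, 0)
  X <- m1 %o% t1 + m2 %o% t2
  rec <- make_recording(X)
  dec <- decompose_signal(rec, 4)
  full <- remove_components(rec, dec, integer(0))
  expect_equal(full$signal, rec$signal, tolerance = 1e-8)
  # removing the dominant component leaves the second mixture
  only2 <- remove_components(rec, dec, 1L)
  expect_equal(only2$signal, m2 %o% t2, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(remove_components(rec, dec, 9L), "out of range")
})

test_that("screen + remove cleans a blink-contaminated recording", {
  m <- small_montage()
  seq <- generate_block(block_spec(n_standards = 40, n_per_deviant = 6,
                                   habituation_len = 2), 4)
  params <- gen_params(noise_sd = 2,
                       mmn_amplitude = c(deviant1 = -3, deviant2 = -3))
  rec <- simulate_recording(seq, params, m, seed = 2)
  rec <- inject_artifacts(rec, blink_rate = 20, blink_amplitude = 120,
                          seed = 3, montage = m)$recording
  rec <- derive_eog(rec)
  rec <- bandpass_filter(rec, filter_length = 4001)
  rec <- resample(rec, 200, anti_alias = FALSE)
  veog <- rec$signal[match("vEOG", rec$channel_names), ]
  heog <- rec$signal[match("hEOG", rec$channel_names), ]
  frontal <- names(which.max(
    mmnpipe:::spatial_weights(m, gen_params(topography_center = c(0, 1.3),
                                            topography_sd = 0.2))))
  before <- abs(cor(rec$signal[match(frontal, rec$channel_names), ], veog))
  expect_gt(before, 0.3)                          # contamination present
  dec <- decompose_signal(rec)
  cleaned <- remove_components(rec, dec,
                               screen_components(dec$timecourses, veog, heog))
  after <- abs(cor(cleaned$signal[match(frontal, rec$channel_names), ], veog))
  expect_lt(after, 0.3)
})

test_that("spherical-spline interpolation reproduces smooth fields", {
  m <- synthetic_montage(128, 0)
  n_ch <- nrow(m$channels)
  # constant field
  rec <- make_recording(matrix(7, n_ch, 3))
  rec$channel_names <- m$channels$name
  rec$roles <- m$channels$role
  out <- interpolate_channels(rec, c("E010", "E050"), m)
  expect_equal(out$signal[match("E010", rec$channel_names), ], rep(7, 3),
               tolerance = 1e-6)
  # first-order harmonic (linear in z)
  z <- m$channels$z
  rec2 <- rec; rec2$signal <- matrix(z, n_ch, 2)
  out2 <- interpolate_channels(rec2, "E020", m)
  err <- abs(out2$signal[match("E020", rec$channel_names), 1] -
             z[match("E020", m$channels$name)])
  expect_lt(err, 0.02 * diff(range(z)))
  # leave-one-out on a smooth synthetic field
  field <- exp(-((m$channels$x - 0.3)^2 + (m$channels$y - 0.2)^2 +
                 (m$channels$z - 0.9)^2))
  rec3 <- rec; rec3$signal <- matrix(field, n_ch, 1)
  out3 <- interpolate_channels(rec3, "E030", m)
  i <- match("E030", m$channels$name)
  expect_lt(abs(out3$signal[i, 1] - field[i]) / diff(range(field)), 0.05)
  # good channels untouched
  expect_equal(out3$signal[-i, 1], field[-i])
  expect_error(interpolate_channels(rec3, m$channels$name[1:126], m),
               "at least 4")
})

test_that("epoching follows the half-open, shift-compensated grid", {
  rate <- 200
  sig <- matrix(seq_len(3000), 1)                # signal value = sample index
  rec <- make_recording(sig, rate,
                        events = data.frame(sample = 2000L, label = "std",
                                            is_deviant = FALSE,
                                            is_habituation = FALSE,
                                            is_post_deviant = FALSE))
  ep <- epoch_recording(rec, divergence_offset = 0)
  expect_equal(dim(ep$data)[3], 170L)            # (0.800 + 0.050) * 200
  t0 <- which(abs(ep$times) < 1e-12)
  expect_equal(ep$data[1, 1, t0], 2005)          # +25 ms trigger shift
  expect_equal(ep$data[1, 1, 1], 2005 - 10)      # tmin = -50 ms

  # deviants lock to the divergence point
  rec$events$is_deviant <- TRUE
  epd <- epoch_recording(rec, divergence_offset = 0.625)
  expect_equal(epd$data[1, 1, t0], 2005 + 125)

  # empty event list -> zero epochs, no error
  rec0 <- rec; rec0$events <- rec$events[0, ]
  expect_equal(dim(epoch_recording(rec0)$data)[1], 0L)

  # out-of-bounds trials are dropped with a logged reason
  rec2 <- make_recording(sig, rate,
                         events = data.frame(sample = c(5L, 2000L),
                                             label = "std",
                                             is_deviant = FALSE,
                                             is_habituation = FALSE,
                                             is_post_deviant = FALSE))
  ep2 <- epoch_recording(rec2, divergence_offset = 0)
  expect_equal(dim(ep2$data)[1], 1L)
  expect_equal(attr(ep2, "dropped")$trial, 1L)

  # habituation / post-deviant flags are excluded
  rec3 <- make_recording(sig, rate,
                         events = data.frame(sample = c(500L, 1000L, 2000L),
                                             label = "std",
                                             is_deviant = FALSE,
                                             is_habituation = c(TRUE, FALSE,
                                                                FALSE),
                                             is_post_deviant = c(FALSE, TRUE,
                                                                 FALSE)))
  expect_equal(dim(epoch_recording(rec3, divergence_offset = 0)$data)[1], 1L)
})

test_that("baseline correction zeroes the baseline window exactly", {
  rate <- 200
  ep <- epoch_recording(
    make_recording(matrix(7, 2, 2000), rate,
                   events = data.frame(sample = 1000L, label = "s",
                                       is_deviant = FALSE,
                                       is_habituation = FALSE,
                                       is_post_deviant = FALSE)),
    divergence_offset = 0)
  bc <- baseline_correct(ep)
  expect_equal(max(abs(bc$data)), 0)             # constant epoch -> zeros

  set.seed(3)
  ep$data <- array(rnorm(length(ep$data)), dim(ep$data))
  bc2 <- baseline_correct(ep)
  sel <- bc2$times >= -0.05 & bc2$times < 0
  expect_lt(max(abs(apply(bc2$data[, , sel, drop = FALSE], c(1, 2), mean))),
            1e-12)
  # ramp minus its baseline mean
  ramp <- seq_len(dim(ep$data)[3])
  ep$data[1, 1, ] <- ramp
  bc3 <- baseline_correct(ep)
  expect_equal(bc3$data[1, 1, ], ramp - mean(ramp[sel]))
  expect_error(baseline_correct(ep, c(-0.5, 0)), "config error")
})

test_that("artifact rejection applies strict thresholds to EEG only", {
  make_ep <- function(trial_chan_fun) {
    d <- array(0, c(3, 2, 40))
    for (i in 1:3) d[i, , ] <- trial_chan_fun(i)
    ep <- mmnpipe:::new_epochs(d, 200, -0.05, 0.15, c("c1", "EOGup"),
                               c("EEG", "EOG"), rep("dev", 3),
                               rep(TRUE, 3), 1:3)
    ep
  }
  # trial 1: range 121 on EEG; trial 2: range exactly 120 with jump exactly
  # 25; trial 3: clean EEG but wild EOG
  steps120 <- cumsum(c(0, rep(25, 4), 20, rep(0, 34)))
  ep <- make_ep(function(i) {
    x <- matrix(0, 2, 40)
    if (i == 1) x[1, ] <- c(rep(0, 20), cumsum(c(rep(24.2, 5)))[1:5],
                            rep(121, 15))
    if (i == 2) x[1, ] <- steps120
    if (i == 3) x[2, ] <- c(rep(0, 10), rep(500, 30))
    x
  })
  out <- reject_artifacts(ep)
  expect_equal(out$kept_mask, c(FALSE, TRUE, TRUE))
  expect_equal(out$reject_reason[1], "range")
  # jump rule: a single 25.5 step with small range
  ep2 <- make_ep(function(i) {
    x <- matrix(0, 2, 40); x[1, ] <- c(rep(0, 20), rep(25.5, 20)); x
  })
  out2 <- reject_artifacts(ep2)
  expect_false(any(out2$kept_mask))
  expect_true(all(out2$reject_reason == "jump"))
})

test_that("rejection is monotone in both thresholds", {
  set.seed(8)
  d <- array(rnorm(20 * 3 * 50, sd = 30), c(20, 3, 50))
  ep <- mmnpipe:::new_epochs(d, 200, -0.05, 0.2, c("a", "b", "c"),
                             rep("EEG", 3), rep("dev", 20), rep(TRUE, 20),
                             1:20)
  kept <- function(mm, jp) reject_artifacts(ep, mm, jp)$kept_mask
  for (mm in c(60, 90, 120)) for (jp in c(20, 40)) {
    expect_true(all(kept(mm, jp) <= kept(mm + 30, jp)))
    expect_true(all(kept(mm, jp) <= kept(mm, jp + 20)))
  }
})

test_that("averaging matches a loop oracle and the MMN difference is exact", {
  set.seed(5)
  d <- array(rnorm(6 * 2 * 30), c(6, 2, 30))
  ep <- mmnpipe:::new_epochs(d, 200, -0.05, 0.1, c("a", "b"),
                             rep("EEG", 2), rep(c("dev", "std"), 3),
                             rep(c(TRUE, FALSE), 3), 1:6)
  erp <- average_erp(ep, "dev")
  loop <- matrix(0, 2, 30)
  cnt <- 0
  for (i in seq_len(6)) if (ep$labels[i] == "dev") {
    loop <- loop + d[i, , ]; cnt <- cnt + 1
  }
  expect_equal(erp$data, loop / cnt, tolerance = 1e-12)
  expect_equal(erp$n_trials, 3L)
  expect_error(average_erp(ep, "nope"), "QC error")

  # two single-sample-style epochs [0] and [2] average to [1]
  d2 <- array(0, c(2, 1, 4)); d2[2, , ] <- 2
  ep2 <- mmnpipe:::new_epochs(d2, 200, 0, 0.02, "a", "EEG",
                              c("x", "x"), c(TRUE, TRUE), 1:2)
  expect_equal(as.vector(average_erp(ep2, "x")$data), rep(1, 4))

  std <- average_erp(ep, "std")
  expect_equal(max(abs(compute_mmn(erp, erp)$data)), 0)
  diffw <- compute_mmn(erp, std)
  expect_equal(diffw$data, erp$data - std$data)
  short <- std; short$data <- std$data[, 1:10]; short$times <- std$times[1:10]
  expect_error(compute_mmn(erp, short), "input error")
})

test_that("filtering and epoching commute on interior samples", {
  set.seed(9)
  rate <- 500
  rec <- make_recording(matrix(rnorm(2 * 5000), 2), rate,
                        events = data.frame(sample = 2500L, label = "s",
                                            is_deviant = FALSE,
                                            is_habituation = FALSE,
                                            is_post_deviant = FALSE))
  f_then_e <- epoch_recording(bandpass_filter(rec, 1, 40,
                                              filter_length = 201),
                              divergence_offset = 0)
  ep <- epoch_recording(rec, divergence_offset = 0)
  ep_rec <- make_recording(ep$data[1, , ], rate)
  e_then_f <- bandpass_filter(ep_rec, 1, 40, filter_length = 201)
  interior <- 150:275
  expect_equal(f_then_e$data[1, , interior],
               e_then_f$signal[, interior], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("the full chain maps a silent recording to all-zero ERPs", {
  m <- small_montage()
  cfg <- small_config()
  seq <- generate_block(block_spec("sicher", c("sicherheit", "sicherkeit"),
                                   30, 5, c(2, 5), 3, 2), 1)
  params <- gen_params(noise_sd = 0, trial_jitter_sd = 0,
                       standard_response_amplitude = 0,
                       mmn_amplitude = c(sicherheit = 0, sicherkeit = 0))
  rec <- simulate_recording(seq, params, m, seed = 1)
  # silent data has zero-variance components, which screening warns about
  ep <- suppressWarnings(preprocess_block(rec, m, cfg$preproc))
  erp <- average_erp(ep, "sicherheit")
  expect_lt(max(abs(erp$data)), 1e-10)
})
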