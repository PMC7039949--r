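test_that("default sweep sets hold 400 repetitions and validate delays", {
  p <- gen_params(seed = 2)
  cond <- make_condition("REC", "ANODIC_FIRST", current = 150)
  ss <- simulate_sweepset(p, cond, delay_tag = 0, seed = 5)
  expect_equal(nrow(ss$sweeps), 400)
  expect_s3_class(ss, "sweep_set")
  expect_error(simulate_sweepset(p, cond, delay_tag = 7), "delay_tag")
})

test_that("simulation is bit-identical under a fixed seed", {
  p <- gen_params(n_sweeps = 5, seed = 9)
  s1 <- simulate_study(p, shapes = "REC", level_multipliers = c(0.9, 1.4),
                       seed = 9)
  s2 <- simulate_study(p, shapes = "REC", level_multipliers = c(0.9, 1.4),
                       seed = 9)
  expect_identical(s1$sweepsets, s2$sweepsets)
  # and sweep-set substreams are reproducible in isolation
  id <- names(s1$sweepsets)[3]
  ss <- s1$sweepsets[[id]]
  again <- simulate_sweepset(p, ss$condition, ss$delay_tag,
                             seed = pulseabr:::derive_seed(9, 3))
  expect_identical(again$sweeps, ss$sweeps)
})

test_that("polarity flips the artifact but not the waves", {
  # make the wave response polarity-independent so the decomposition is
  # exact: equal thresholds and no polarity latency offset
  p <- gen_params(noise_sd = 0, polarity_threshold_ratio = 1,
                  latency_model = list(
                    shape_offset_us = c(REC = 0, RAMP_UP = 0,
                                        RAMP_DOWN = 0, RAMP_LONG = 0),
                    polarity_offset_us = c(ANODIC_FIRST = 0,
                                           CATHODIC_FIRST = 0),
                    db_slope_us = -10),
                  seed = 1)
  cur <- 3.36 * 1000 / 25
  ca <- make_condition("REC", "ANODIC_FIRST", current = cur)
  cc <- make_condition("REC", "CATHODIC_FIRST", current = cur)
  sa <- simulate_sweepset(p, ca, 0, seed = 1)$sweeps[1, ]
  sc <- simulate_sweepset(p, cc, 0, seed = 1)$sweeps[1, ]
  wave <- (sa + sc) / 2          # artifact cancels
  artifact <- (sa - sc) / 2      # waves cancel
  # subthreshold simulation isolates the artifact exactly
  p_sub <- p
  art_only <- simulate_sweepset(
    p, make_condition("REC", "ANODIC_FIRST", current = cur * 1e-3),
    0, seed = 1)$sweeps[1, ] * 1e3
  expect_equal(artifact, art_only, tolerance = 1e-9)
  expect_gt(max(abs(wave)), 0.5)  # waves really present
  # below threshold the sweeps contain artifact only
  lo <- simulate_sweepset(
    p, make_condition("REC", "ANODIC_FIRST", current = 1 * 1000 / 25),
    0, seed = 1)$sweeps[1, ]
  expect_equal(lo, art_only * (1000 / 25) / cur, tolerance = 1e-9)
})

test_that("exponential tail appears only in long-gap conditions", {
  p <- gen_params(noise_sd = 0, seed = 1)
  cur <- 100
  short <- simulate_sweepset(
    p, make_condition("REC", "ANODIC_FIRST", interphase_gap = 10,
                      current = cur), 0, seed = 1)
  long <- simulate_sweepset(
    p, make_condition("REC", "ANODIC_FIRST", interphase_gap = 2900,
                      current = cur), 0, seed = 1)
  dt <- 1e6 / p$sampling_rate
  t_short <- short$t_start + (seq_len(ncol(short$sweeps)) - 1) * dt
  t_long <- long$t_start + (seq_len(ncol(long$sweeps)) - 1) * dt
  # at ~2 ms the fast artifact is dead; only the tail can be there
  i_s <- which(t_short > 1900 & t_short < 2100)
  i_l <- which(t_long > 1900 & t_long < 2100)
  expect_lt(max(abs(short$sweeps[1, i_s])), 0.2)
  expect_gt(max(abs(long$sweeps[1, i_l])), 1)
})

test_that("averaging 400 sweeps shrinks noise by sqrt(n)", {
  p <- params_wave_only(noise_sd = 2, seed = 31)
  cond <- make_condition("REC", "ANODIC_FIRST", current = 1)  # subthreshold
  ss <- simulate_sweepset(p, cond, 0, seed = 31)
  avg <- colMeans(ss$sweeps)
  expect_lt(abs(sd(avg) / (2 / sqrt(400)) - 1), 0.10)
})

test_that("find_wave recovers latency and amplitude from clean sweeps", {
  # noise-free, artifact-free, single wave: latency within one effective
  # sample (5.12 us), amplitude within 1%
  p <- params_wave_only()
  for (charge in c(4, 6)) {
    cond <- make_condition("REC", "ANODIC_FIRST",
                           current = charge * 1000 / 25)
    sets <- delay_sets(p, cond)
    traces <- lapply(sets, function(s) {
      tr <- epoch_average(s)
      tr$delay_tag <- s$delay_tag
      tr
    })
    tr <- interleave_upsample(traces)
    wm <- find_wave(tr, "II")
    true_lat <- true_wave_latency(p, "REC", "ANODIC_FIRST", charge)
    true_amp <- true_wave_amplitude(p, "REC", "ANODIC_FIRST", charge)
    expect_lt(abs(wm$peak_latency - true_lat), 5.12e-3)
    expect_lt(abs(wm$amplitude / true_amp - 1), 0.01)
    expect_gt(wm$trough_latency, wm$peak_latency)
  }
})

test_that("facial-nerve onset flags levels in study metadata", {
  p <- gen_params(noise_sd = 0, facial_nerve_onset = 5, seed = 1)
  st <- simulate_study(p, shapes = "REC", polarities = "ANODIC_FIRST",
                       seed = 1)
  lv <- st$ground_truth$levels
  expect_true(all(lv$above_facial_nerve == (lv$charge >= 5)))
  conds <- vapply(st$sweepsets, function(s) s$condition$above_facial_nerve,
                  logical(1))
  charges <- vapply(st$sweepsets, function(s) s$condition$charge, numeric(1))
  expect_true(all(conds == (charges >= 5)))
})

test_that("growth and latency models respect their bounds", {
  p <- gen_params(seed = 1, growth = list(
    REC = list(threshold_charge = 2, slope = 3, knee = 6,
               saturation_slope = -0.5)))
  q <- c(1, 2, 4, 6, 10)
  a <- true_wave_amplitude(p, "REC", "CATHODIC_FIRST", q)
  expect_equal(a, c(0, 0, 6, 12, 12 - 0.5 * 4))
  # anodic threshold is 1.10x the cathodic one
  expect_equal(true_wave_amplitude(p, "REC", "ANODIC_FIRST", 2.2), 0)
  expect_gt(true_wave_amplitude(p, "REC", "ANODIC_FIRST", 2.3), 0)
  # latency decreases with level
  l1 <- true_wave_latency(p, "REC", "CATHODIC_FIRST", 2.5)
  l2 <- true_wave_latency(p, "REC", "CATHODIC_FIRST", 5)
  expect_lt(l2, l1)
})
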