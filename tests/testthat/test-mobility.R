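# Windowed RMSF and differential mobility calling.

test_that("window_partition arithmetic matches frame spacing and span", {
  ref <- fixture_reference(10)
  # 4000 frames at 10 ps: last 40 ns in 100-ps windows -> 400 x 10 frames
  tr <- synth_trajectory(ref, 0.1, n_frames = 4000,
                         frame_interval_ps = 10, seed = 1)
  w <- window_partition(tr, span_last_ns(tr, 40), window_ps = 100)
  expect_length(w, 400)
  expect_true(all(lengths(w) == 10))
  expect_equal(sort(unlist(w)), 1:4000)
  # full span as a single window
  w1 <- window_partition(tr, window_ps = 40000)
  expect_length(w1, 1)
  expect_length(w1[[1]], 4000)
})

test_that("windows with fewer than 2 frames are an error (RMSF undefined)", {
  ref <- fixture_reference(10)
  tr <- synth_trajectory(ref, 0.1, n_frames = 400,
                         frame_interval_ps = 100, seed = 1)
  expect_error(window_partition(tr, span_last_ns(tr, 40), window_ps = 100),
               "fewer than 2 frames")
  expect_error(span_last_ns(tr, 50), "longer than trajectory")
  expect_error(window_partition(tr, c(0, 1e6), window_ps = 100),
               "exceeds trajectory")
})

test_that("window averages: static, mirrored-pair, and iterated oracle", {
  ref <- fixture_reference(20)
  static <- synth_trajectory(ref, 0, n_frames = 4, seed = 1)
  sel <- select_atoms(static$topology)
  avg <- window_average_structure(static, 1:4, sel)
  expect_equal(avg, frame_coords(static, 1), tolerance = 1e-10,
               ignore_attr = TRUE)

  # two frames displaced +d and -d about r; the average is r up to a rigid
  # transform (the result lives in the first frame's orientation)
  set.seed(42)
  d <- matrix(rnorm(nrow(ref$atom) * 3, sd = 0.02), ncol = 3)
  coords <- array(NA_real_, dim = c(2, nrow(ref$atom), 3))
  coords[1, , ] <- ref$xyz + d
  coords[2, , ] <- ref$xyz - d
  mirr <- as_md_traj(ref, coords)
  avg2 <- window_average_structure(mirr, 1:2, sel)
  realigned <- apply_transform(kabsch_fit(avg2, ref$xyz), avg2)
  expect_lt(max(abs(realigned - ref$xyz)), 1e-3)

  noisy <- synth_trajectory(ref, 0.3, n_frames = 10, seed = 2)
  avg3 <- window_average_structure(noisy, 1:10, sel)
  oracle <- oracle_iterated_average(noisy, 1:10, sel)
  expect_lt(max(abs(avg3 - oracle)), 1e-3)
})

test_that("static trajectory has an all-zero RMSF profile", {
  ref <- fixture_reference(15)
  tr <- synth_trajectory(ref, 0, n_frames = 40, seed = 1)
  pr <- windowed_rmsf(tr, window_ps = 100)
  expect_equal(pr$rmsf, rep(0, 15), tolerance = 1e-10)
  expect_equal(pr$n_windows, 4)
})

test_that("isotropic fluctuations recover the closed form within 5%", {
  ref <- synth_reference(60, seed = 1)
  tr <- synth_trajectory(ref, 0.5, n_frames = 1000,
                         frame_interval_ps = 10, seed = 3)
  pr <- windowed_rmsf(tr, window_ps = 100)   # 100 windows of 10 frames
  expected <- expected_windowed_rmsf(0.5, 10)
  # at 100 windows the per-residue estimate still carries ~1.4% sampling
  # noise plus the small superposition absorption, so allow 7% per residue
  # and 3% on the profile mean (the acceptance suite tightens this at 400
  # windows)
  expect_true(all(abs(pr$rmsf / expected - 1) < 0.07))
  expect_equal(mean(pr$rmsf), expected, tolerance = 0.03)
  set.seed(9)
  expect_equal(expected, mc_windowed_rmsf(0.5, 10), tolerance = 0.02)
})

test_that("RMSF is invariant to rigid-body motion and scales with sigma", {
  ref <- synth_reference(40, seed = 1)
  base <- synth_trajectory(ref, 0.4, n_frames = 600,
                           frame_interval_ps = 10, seed = 5)
  pr_base <- windowed_rmsf(base, window_ps = 100)
  drift <- synth_trajectory(
    ref, fluc_spec(1:40, 0.4, rigid_body = list(step_deg = 3, step_A = 0.5)),
    n_frames = 600, frame_interval_ps = 10, seed = 5)
  pr_drift <- windowed_rmsf(drift, window_ps = 100)
  expect_equal(mean(pr_drift$rmsf), mean(pr_base$rmsf), tolerance = 0.05)

  # homogeneity: doubling sigma doubles the profile
  dbl <- synth_trajectory(ref, 0.8, n_frames = 600,
                          frame_interval_ps = 10, seed = 5)
  pr_dbl <- windowed_rmsf(dbl, window_ps = 100)
  expect_equal(pr_dbl$rmsf / pr_base$rmsf, rep(2, 40), tolerance = 0.05)
})

test_that("windowing suppresses slow drift relative to full-span RMSF", {
  ref <- synth_reference(30, seed = 1)
  two_ts <- synth_trajectory(
    ref, fluc_spec(1:30, 0.2,
                   slow_drift = list(amplitude_A = 1.5, period_ps = 4000)),
    n_frames = 800, frame_interval_ps = 10, seed = 6)
  windowed <- windowed_rmsf(two_ts, window_ps = 100)
  full <- windowed_rmsf(two_ts, window_ps = 8000)  # single window
  expect_equal(full$n_windows, 1)
  expect_true(mean(windowed$rmsf) < mean(full$rmsf))
  # the slow mode should dominate the full-span statistic
  expect_gt(mean(full$rmsf) / mean(windowed$rmsf), 1.5)
})

test_that("bio3d's rmsf agrees on a single pre-aligned window", {
  ref <- synth_reference(25, seed = 1)
  tr <- synth_trajectory(ref, 0.3, n_frames = 50, frame_interval_ps = 10,
                         seed = 8)
  sel <- select_atoms(tr$topology)
  pr <- windowed_rmsf(tr, sel, window_ps = 500)  # one window
  # oracle: align frames to the window average with bio3d, then its rmsf
  avg <- window_average_structure(tr, 1:50, sel)
  xyz <- t(vapply(1:50, function(f) {
    m <- frame_coords(tr, f)[sel, ]
    ft <- kabsch_fit(m, avg[sel, ])
    as.vector(t(apply_transform(ft, m)))
  }, numeric(length(sel) * 3)))
  # bio3d::rmsf uses the (n-1) sample denominator; rescale to population
  expect_equal(pr$rmsf, bio3d::rmsf(xyz) * sqrt(49 / 50), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("hand-computed differential mobility calls and labels", {
  mkprof <- function(vals) {
    structure(list(residue_ids = seq_along(vals), rmsf = vals,
                   n_windows = 1, window_ps = 100, span = c(0, 100)),
              class = "rmsf_profile")
  }
  base <- mkprof(rep(1, 100))
  delta <- c(1, -1, rep(0, 98))
  calls <- differential_mobility(mkprof(rep(1, 100) + delta), base)
  # mean = 0, population SD = sqrt(2/100) ~ 0.1414
  expect_equal(attr(calls, "mean_delta"), 0)
  expect_equal(attr(calls, "sd_delta"), sqrt(0.02))
  expect_equal(as.character(calls$label[1]), "increased")
  expect_equal(as.character(calls$label[2]), "decreased")
  expect_true(all(calls$label[3:100] == "unchanged"))

  # identical profiles: sd = 0, everything unchanged (documented degenerate)
  same <- differential_mobility(base, base)
  expect_true(all(same$label == "unchanged"))
  expect_equal(attr(same, "sd_delta"), 0)

  bad <- mkprof(rep(1, 99))
  expect_error(differential_mobility(bad, base), "symmetric difference")
})

test_that("planted high-sigma residues are recovered exactly", {
  ref <- synth_reference(80, seed = 1)
  sig <- rep(0.4, 80); sig[50:55] <- 0.8
  tr_ref <- synth_trajectory(ref, 0.4, n_frames = 1500,
                             frame_interval_ps = 10, seed = 11)
  tr_var <- synth_trajectory(ref, sig, n_frames = 1500,
                             frame_interval_ps = 10, seed = 12)
  calls <- differential_mobility(
    windowed_rmsf(tr_var, window_ps = 100),
    windowed_rmsf(tr_ref, window_ps = 100))
  fl <- flagged_residues(calls)
  expect_setequal(fl$residue_id[fl$label == "increased"], 50:55)
  expect_length(fl$residue_id[fl$label == "decreased"], 0)
})
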