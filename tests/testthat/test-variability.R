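test_that("mean cycle averages states and respects symmetry", {
  cfg <- generator_config()
  tpl <- template_knee_cycle(cfg)
  # identical trials: the mean equals any trial
  mc <- mean_cycle(list(tpl, tpl, tpl))
  expect_equal(mc$theta, tpl$theta, tolerance = 1e-12)
  expect_equal(mc$k, tpl$k, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(mc$proj, tpl$proj, tolerance = 1e-9)
  # two trials with axes tilted symmetrically about Z average back to Z
  mk <- function(sign) {
    R <- array(NA_real_, c(3, 3, 101))
    ax <- c(sign * sin(5 * pi / 180), 0, cos(5 * pi / 180))
    for (i in 1:101) R[, , i] <- rotation_from_attitude(20 + i / 10, ax)
    gait_cycle(R)
  }
  m2 <- mean_cycle(list(mk(1), mk(-1)))
  expect_equal(unname(m2$k[50, ]), c(0, 0, 1), tolerance = 1e-9)
  # sampled mean stays near the template curve
  ds <- generate_dataset(generator_config(sd_theta = 2, n_sessions = 5,
                                          n_trials = 8, seed = 3))
  m3 <- mean_cycle(ds)
  sem <- 2 / sqrt(40)
  expect_lt(max(abs(m3$theta - tpl$theta)), 3 * sem + 1e-9)
  expect_error(mean_cycle(list()), "no trials")
})

test_that("angular deviation is the arc between unit vectors", {
  expect_equal(angular_deviation(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(angular_deviation(c(1, 0, 0), c(0, 0, 1)), 90)
  k <- c(sin(5 * pi / 180), 0, cos(5 * pi / 180))
  expect_equal(angular_deviation(k, c(0, 0, 1)), 5, tolerance = 1e-9)
  expect_error(angular_deviation(c(1, 1, 0), c(0, 0, 1)), "unit")
})

test_that("RMSD table matches hand computation and degenerates to zero", {
  # zero-noise dataset: all entries zero
  ds0 <- generate_dataset(generator_config(n_sessions = 2, n_trials = 2))
  tab0 <- rmsd_table(ds0)
  # zero up to acos() roundoff in the axis-orientation row
  expect_lt(max(abs(c(tab0$inter_session_rmsd, tab0$intra_session_rmsd))),
            1e-6)
  # two constant-offset trials in one session: deviations +/-2 -> RMSD 2
  cfg <- generator_config()
  tpl <- template_knee_cycle(cfg)
  shift_theta <- function(cycle, target) {
    R <- cycle$R
    for (i in 1:101) R[, , i] <- rotation_from_attitude(target, cycle$k[i, ])
    gait_cycle(R, session_id = 1L, trial_id = target)
  }
  ds <- structure(list(sessions = list(list(shift_theta(tpl, 10),
                                            shift_theta(tpl, 14))),
                       template = tpl, config = cfg),
                  class = "jcs_dataset")
  expect_warning(tab <- rmsd_table(ds), "single session")
  expect_equal(tab$intra_session_rmsd[1], 2, tolerance = 1e-9)
  expect_equal(tab$inter_session_rmsd[1], 2, tolerance = 1e-9)
})

test_that("mixed-noise datasets keep projected and Cardan variability close", {
  ds <- generate_dataset(generator_config(sd_theta = 3, cone_k = 3,
                                          cone_e1_session = 3,
                                          cone_e3_session = 3, seed = 29))
  tab <- rmsd_table(ds)
  for (col in c("inter_session_rmsd", "intra_session_rmsd")) {
    expect_lt(abs(tab[[col]][3] - tab[[col]][4]) / tab[[col]][3], 0.2) # theta1
    expect_lt(abs(tab[[col]][7] - tab[[col]][8]) / tab[[col]][7], 0.2) # theta3
  }
  # any nonzero session-level dispersion: inter >= intra for every row
  expect_true(all(tab$inter_session_rmsd >= tab$intra_session_rmsd - 1e-9))
})

test_that("summarize_table reports mean and population SD", {
  expect_equal(unname(summarize_table(c(2, 2, 2))), c(2, 0))
  expect_error(summarize_table(numeric(0)), "non-empty")
  s <- summarize_table(c(1, 3))
  expect_equal(unname(s), c(2, 1)) # population (divisor n) SD
})

test_that("experimental SD curves track the generated dispersion", {
  ds0 <- generate_dataset(generator_config(n_sessions = 1, n_trials = 3))
  sd0 <- experimental_sd_curves(ds0)
  expect_equal(max(sd0$cardan), 0, tolerance = 1e-12)
  cfg <- generator_config(sd_theta = 3, varus_offset = 0, rotation_offset = 0,
                          n_sessions = 1, n_trials = 40, seed = 19)
  ds <- generate_dataset(cfg)
  sdc <- experimental_sd_curves(ds)
  # pure hinge with theta noise: the theta1 corridor sits near 3 degrees
  expect_lt(abs(mean(sdc$cardan[, 1]) - 3) / 3, 0.2)
  # session-level e1 (thigh frame) tilt only: theta2 corridor elevated over
  # the whole cycle at the tan(cone) scale -- the constant-offset channel of
  # a frame tilt dominates, on top of the flexion-scaled cross-talk
  cfg2 <- generator_config(cone_e1_session = 5, n_sessions = 8, n_trials = 1,
                           seed = 23)
  ds2 <- generate_dataset(cfg2)
  sd2 <- experimental_sd_curves(ds2)
  scale <- atan(tan(5 * pi / 180)) * 180 / pi # ~5 deg per tilt component
  expect_gt(min(sd2$cardan[, 2]), 0.3 * scale)
  expect_lt(abs(mean(sd2$cardan[, 2]) - scale) / scale, 0.6)
})

test_that("agreement labels follow the five-symbol ratio scheme", {
  x <- rep(1, 101)
  expect_equal(classify_agreement(x, x)$label, rep("0", 3))
  expect_equal(classify_agreement(3 * x, x)$label, rep("++", 3))
  expect_equal(classify_agreement(0.6 * x, x)$label, rep("-", 3))
  expect_equal(classify_agreement(0.3 * x, x)$label, rep("--", 3))
  expect_equal(classify_agreement(1.5 * x, x)$label, rep("+", 3))
  # indeterminate when the experimental corridor is numerically zero
  out <- classify_agreement(x, rep(0, 101))
  expect_true(all(is.na(out$label)))
  # hinge dataset with theta-only analytic input: theta2 in swing is
  # highly underestimated relative to real axis-driven dispersion
  ds <- generate_dataset(generator_config(cone_e1_session = 5, cone_k = 3,
                                          n_sessions = 6, n_trials = 2,
                                          seed = 31))
  sdc <- experimental_sd_curves(ds)
  up <- suppressWarnings( # low-flexion frames leave the kz > 0 domain
    propagate_sequence(mean_cycle(ds), uncertainty_inputs(5, 0, 0, 0)))
  cmp <- classify_agreement(up$combined[, 2], sdc$cardan[, 2])
  # high-flexion swing: axis-driven cross-talk dispersion dwarfs what a
  # rotation-angle uncertainty alone predicts
  expect_equal(cmp$label[cmp$phase == "swing_61.8_85"], "--")
})
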