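ref_pose <- c(theta = 60, kx = 0, ky = 0, e1x = 0, e1y = 0, e3x = 0, e3z = 0)

test_that("hinge pose propagates u(theta) straight into u(theta1)", {
  pr <- propagate(ref_pose, uncertainty_inputs(5, 0, 0, 0))
  expect_equal(unname(pr$combined), c(5, 0, 0), tolerance = 1e-12)
  pr <- propagate(ref_pose, uncertainty_inputs(0, 0, 0, 0))
  expect_equal(unname(pr$combined), c(0, 0, 0))
})

test_that("combined squared uncertainty is the sum of per-source squares", {
  set.seed(31)
  u <- uncertainty_inputs(2, 5, 3, 4)
  for (i in 1:20) {
    pr <- propagate(random_pose_params(), u)
    expect_equal(unname(pr$combined^2), unname(rowSums(pr$per_source^2)),
                 tolerance = 1e-9)
    expect_true(all(pr$per_source >= 0))
  }
})

test_that("outputs scale linearly in the input standard uncertainties", {
  set.seed(32)
  p <- random_pose_params()
  # build inputs whose component standard uncertainties are exactly halved
  half_cone <- function(a)
    atan(tan(a * pi / 180) / 2) * 180 / pi
  u1 <- uncertainty_inputs(4, 6, 5, 3)
  u2 <- uncertainty_inputs(2, half_cone(6), half_cone(5), half_cone(3))
  expect_equal(propagate(p, u1)$combined, 2 * propagate(p, u2)$combined,
               tolerance = 1e-12)
})

test_that("outputs are monotonically non-decreasing in each input", {
  set.seed(33)
  p <- random_pose_params()
  base <- uncertainty_inputs(2, 2, 2, 2)
  b <- propagate(p, base)$combined
  for (arg in c("u_theta", "alpha_k", "alpha_e1", "alpha_e3")) {
    args <- list(u_theta = 2, alpha_k = 2, alpha_e1 = 2, alpha_e3 = 2)
    args[[arg]] <- 4
    up <- propagate(p, do.call(uncertainty_inputs, args))$combined
    expect_true(all(up >= b - 1e-12))
  }
})

test_that("hinge template cycle keeps u(theta1) constant under u(theta)", {
  hin <- hinge_template_cycle()
  up <- propagate_sequence(hin, uncertainty_inputs(5, 0, 0, 0))
  expect_equal(unname(up$combined[, 1]), rep(5, 101), tolerance = 1e-9)
  expect_equal(unname(up$combined[, 2]), rep(0, 101), tolerance = 1e-12)
  expect_equal(unname(up$combined[, 3]), rep(0, 101), tolerance = 1e-12)
})

test_that("axis-cone cross-talk on theta2 peaks with flexion", {
  hin <- hinge_template_cycle()
  up <- propagate_sequence(hin, uncertainty_inputs(0, 0, 5, 0))
  u2 <- up$combined[, 2]
  expect_equal(which.max(u2), which.max(abs(hin$theta)))
  # degenerate frames report zero axis-term uncertainty, flagged
  expect_true(all(u2[hin$degenerate] == 0))
  expect_true(any(up$degenerate))
})

test_that("per-source curves add in quadrature framewise", {
  tpl <- template_knee_cycle()
  up <- propagate_sequence(tpl, uncertainty_inputs(2, 5, 5, 10))
  tot2 <- apply(up$per_source^2, c(1, 2), sum)
  expect_equal(up$combined^2, tot2, tolerance = 1e-9)
})

test_that("per-source curves equal independent propagation of each input", {
  tpl <- template_knee_cycle()
  joint <- propagate_sequence(tpl, uncertainty_inputs(2, 5, 3, 4))
  alone <- list(
    theta = propagate_sequence(tpl, uncertainty_inputs(2, 0, 0, 0)),
    k = propagate_sequence(tpl, uncertainty_inputs(0, 5, 0, 0)),
    e1 = propagate_sequence(tpl, uncertainty_inputs(0, 0, 3, 0)),
    e3 = propagate_sequence(tpl, uncertainty_inputs(0, 0, 0, 4)))
  for (src in names(alone))
    expect_equal(joint$per_source[, , src], alone[[src]]$combined,
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("uncertainty summary and sweep behave sensibly", {
  tpl <- template_knee_cycle()
  sw <- propagate_sweep(tpl, c(2, 5, 10))
  expect_named(sw, c("u2", "u5", "u10"))
  expect_true(all(sw$u5$combined >= sw$u2$combined - 1e-12, na.rm = TRUE))
  expect_true(all(sw$u10$combined >= sw$u5$combined - 1e-12, na.rm = TRUE))
  s <- summary(sw$u5)
  expect_named(s, c("stance", "swing"))
  expect_true(all(unlist(s) >= 0))
})
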