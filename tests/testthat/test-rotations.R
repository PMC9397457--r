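test_that("ZXY Cardan composition matches closed forms and stated entries", {
  expect_equal(compose_cardan_zxy(0, 0, 0), diag(3), tolerance = 1e-12)
  expect_equal(compose_cardan_zxy(45, 0, 0), rz_deg(45), tolerance = 1e-12)
  # structural entries of the ZXY matrix
  for (ang in list(c(30, 10, 5), c(-20, 25, 40), c(70, -35, -10))) {
    R <- compose_cardan_zxy(ang[1], ang[2], ang[3])
    expect_no_error(check_rotation(R))
    a <- ang * pi / 180
    expect_equal(R[3, 2], sin(a[2]), tolerance = 1e-12)
    expect_equal(R[, 2], c(-sin(a[1]) * cos(a[2]), cos(a[1]) * cos(a[2]),
                           sin(a[2])), tolerance = 1e-12)
  }
})

test_that("Cardan extraction round-trips composition away from gimbal lock", {
  expect_equal(unname(extract_cardan_zxy(diag(3))), c(0, 0, 0))
  expect_equal(unname(extract_cardan_zxy(rz_deg(30))), c(30, 0, 0),
               tolerance = 1e-12)
  expect_equal(unname(extract_cardan_zxy(compose_cardan_zxy(12.3, -4.5, 7.8))),
               c(12.3, -4.5, 7.8), tolerance = 1e-9)
  set.seed(42)
  for (i in 1:50) {
    ang <- c(stats::runif(1, -179, 179), stats::runif(1, -88, 88),
             stats::runif(1, -179, 179))
    got <- extract_cardan_zxy(compose_cardan_zxy(ang[1], ang[2], ang[3]))
    expect_equal(unname(got), ang, tolerance = 1e-9)
  }
  expect_error(extract_cardan_zxy(compose_cardan_zxy(10, 90, 20)), "gimbal")
})

test_that("attitude extraction and Rodrigues reconstruction are inverse", {
  id <- attitude_from_rotation(diag(3))
  expect_equal(id$theta, 0)
  expect_equal(id$k, c(0, 0, 1))
  expect_true(id$degenerate)
  att <- attitude_from_rotation(rz_deg(30))
  expect_equal(att$theta, 30, tolerance = 1e-9)
  expect_equal(att$k, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(rotation_from_attitude(0, c(1, 0, 0)), diag(3))
  expect_equal(rotation_from_attitude(90, c(0, 0, 1)), rz_deg(90),
               tolerance = 1e-12)
  # dual-implementation oracle for the Rodrigues form
  k <- c(1, 1, 1) / sqrt(3)
  expect_equal(rotation_from_attitude(37, k), quaternion_rotation(37, k),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:60) {
    R <- random_rotation(1, 179)
    att <- attitude_from_rotation(R)
    expect_false(att$degenerate)
    expect_equal(sqrt(sum(att$k^2)), 1, tolerance = 1e-9)
    expect_true(att$theta >= 0 && att$theta <= 180)
    expect_equal(rotation_from_attitude(att), R, tolerance = 1e-8)
  }
  # near-180-degree branch
  R <- rotation_from_attitude(179.9995, c(0.6, -0.8, 0))
  att <- attitude_from_rotation(R)
  expect_equal(rotation_from_attitude(att), R, tolerance = 1e-7)
  expect_error(rotation_from_attitude(30, c(1, 1, 0)), "unit")
})

test_that("joint axes follow the e1/e3/floating-axis construction", {
  ax <- joint_axes_from_rotation(diag(3))
  expect_equal(ax$e1, c(0, 0, 1))
  expect_equal(ax$e3, c(0, 1, 0))
  expect_equal(ax$e2, c(1, 0, 0))
  ax <- joint_axes_from_rotation(rz_deg(60))
  expect_equal(ax$e3, c(-sin(pi / 3), cos(pi / 3), 0), tolerance = 1e-12)
  expect_equal(ax$e2, c(cos(pi / 3), sin(pi / 3), 0), tolerance = 1e-12)
  # orthogonality of the floating axis, non-degenerate mixed product
  set.seed(3)
  for (i in 1:40) {
    R <- compose_cardan_zxy(stats::runif(1, -90, 90), stats::runif(1, -30, 30),
                            stats::runif(1, -45, 45))
    ax <- joint_axes_from_rotation(R)
    expect_equal(sum(ax$e2 * ax$e1), 0, tolerance = 1e-9)
    expect_equal(sum(ax$e2 * ax$e3), 0, tolerance = 1e-9)
    expect_gt(abs(sum((ax$e1[c(2, 3, 1)] * ax$e2[c(3, 1, 2)] -
                         ax$e1[c(3, 1, 2)] * ax$e2[c(2, 3, 1)]) * ax$e3)),
              1e-3)
  }
  # shank long axis aligned with the flexion axis
  Rdeg <- compose_cardan_zxy(0, 90 - 1e-9, 0)
  expect_error(joint_axes_from_rotation(Rdeg), "degenerate")
})

test_that("attitude projection satisfies the decomposition identity", {
  # hinge: projection equals Cardan angles exactly
  for (th in c(10, 37, 60, 85)) {
    R <- rz_deg(th)
    pr <- project_attitude(attitude_from_rotation(R),
                           joint_axes_from_rotation(R))
    expect_equal(unname(pr), c(th, 0, 0), tolerance = 1e-9)
  }
  # zero rotation projects to zero
  ax <- joint_axes_from_rotation(compose_cardan_zxy(15, 5, 5))
  expect_equal(unname(project_attitude(list(theta = 0, k = c(0, 0, 1)), ax)),
               c(0, 0, 0))
  # decomposition identity theta1 e1 + theta2 e2 + theta3 e3 = theta k
  set.seed(11)
  for (i in 1:60) {
    R <- compose_cardan_zxy(stats::runif(1, -80, 80), stats::runif(1, -25, 25),
                            stats::runif(1, -40, 40))
    att <- attitude_from_rotation(R)
    ax <- joint_axes_from_rotation(R)
    pr <- project_attitude(att, ax)
    lhs <- pr[1] * ax$e1 + pr[2] * ax$e2 + pr[3] * ax$e3
    expect_equal(unname(lhs), att$theta * att$k, tolerance = 1e-9)
  }
  # orthonormal basis reduces to plain dot products
  att <- list(theta = 20, k = c(0.1, 0.1, sqrt(1 - 0.02)))
  ortho <- list(e1 = c(0, 0, 1), e2 = c(1, 0, 0), e3 = c(0, 1, 0))
  expect_equal(unname(project_attitude(att, ortho)),
               20 * c(att$k[3], att$k[1], att$k[2]), tolerance = 1e-12)
})

test_that("relative rotation reproduces the dot-product table", {
  S <- random_rotation()
  expect_equal(relative_rotation(S, S), diag(3), tolerance = 1e-12)
  expect_equal(relative_rotation(diag(3), rz_deg(25)), rz_deg(25))
  set.seed(5)
  for (i in 1:20) {
    T <- random_rotation(); S <- random_rotation()
    R <- relative_rotation(T, S)
    # entry (i, j) is the dot product of shank axis j with thigh axis i
    tab <- matrix(NA_real_, 3, 3)
    for (a in 1:3) for (b in 1:3) tab[a, b] <- sum(S[, b] * T[, a])
    expect_equal(R, tab, tolerance = 1e-12)
    expect_no_error(check_rotation(R, tol = 1e-9))
  }
})

test_that("axis continuity resolves the (theta, k) sign ambiguity", {
  tpl <- template_knee_cycle()
  # already continuous: idempotent
  tpl2 <- enforce_axis_continuity(tpl)
  expect_equal(tpl2$theta, tpl$theta)
  expect_equal(tpl2$k, tpl$k)
  dots <- rowSums(tpl$k[-101, ] * tpl$k[-1, ])
  expect_true(all(dots > 0))
  # a manually injected sign flip is repaired with theta * k preserved
  flipped <- tpl
  flipped$k[50, ] <- -flipped$k[50, ]
  flipped$theta[50] <- -flipped$theta[50]
  fixed <- enforce_axis_continuity(flipped)
  expect_equal(fixed$k, tpl$k)
  expect_equal(fixed$theta, tpl$theta)
  expect_equal(fixed$proj, tpl$proj, tolerance = 1e-9)
  # hinge cycle passing near zero flexion: continuous interpolated axis
  hin <- hinge_template_cycle()
  expect_true(any(hin$degenerate))
  dots <- rowSums(hin$k[-101, ] * hin$k[-1, ])
  expect_true(all(dots > 0))
})

test_that("projected-vs-Cardan gap follows the quadratic cross-term scaling", {
  # the two representations agree to first order; their gap is a second-order
  # cross term ~ theta1 * (theta2, theta3) / 2 (radians)
  gap <- function(varus, rot) {
    tpl <- template_knee_cycle(generator_config(varus_offset = varus,
                                                rotation_offset = rot))
    max(abs(tpl$proj - tpl$cardan))
  }
  bound <- function(varus, rot) {
    (60 * pi / 180) * ((abs(varus) + abs(rot)) * pi / 180) / 2 * 180 / pi
  }
  g1 <- gap(2, 5)
  expect_lt(g1, 1.2 * bound(2, 5))
  # halving the offsets roughly halves the gap (it is linear in the
  # off-flexion angles at fixed flexion)
  g2 <- gap(1, 2.5)
  expect_lt(g2, 0.65 * g1)
  # in the small-rotation regime the representations agree closely
  tpl <- template_knee_cycle(generator_config(varus_offset = 1,
                                              rotation_offset = 2))
  sel <- abs(tpl$theta) <= 15
  expect_lt(max(abs(tpl$proj[sel, ] - tpl$cardan[sel, ])), 0.25)
})
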