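# camera projection, simulated detection, pose estimation

test_that("perspective projection obeys the pinhole identities", {
  cam <- camera_model(focal_px = 1000, image_px = c(2000, 2000),
                      principal_px = c(0, 0))
  # optical axis -> principal point at any depth
  expect_equal(project(cam, rbind(c(0, 0, 100), c(0, 0, 5000))),
               rbind(c(0, 0), c(0, 0)))
  # unit-slope ray
  expect_equal(project(cam, c(300, 0, 300)), cbind(1000, 0),
               ignore_attr = TRUE)
  # doubling depth halves the offset
  p1 <- project(cam, c(50, -30, 400))
  p2 <- project(cam, c(50, -30, 800))
  expect_equal(p2, p1 / 2)
  expect_error(project(cam, c(0, 0, -10)), "behind-camera")
  expect_error(camera_model(principal_px = c(-5, 10)), "principal")
})

test_that("observations are exact at zero noise and reproducible by seed", {
  cam <- overhead_camera(400)
  asm <- needle_assembly()
  pose <- rigid_transform(rot_axis_angle(c(1, 0, 0), 0.2), c(10, -5, 20))
  o0 <- observe(cam, asm$layout, pose, sigma_px = 0)
  expect_equal(o0$points, project(cam, transform_points(pose, asm$layout)),
               ignore_attr = TRUE)
  o1 <- observe(cam, asm$layout, pose, sigma_px = 1, seed = 33)
  o2 <- observe(cam, asm$layout, pose, sigma_px = 1, seed = 33)
  expect_identical(o1, o2)
  expect_false(identical(o1$points,
                         observe(cam, asm$layout, pose, 1, seed = 34)$points))
})

test_that("observation noise has the requested scale", {
  cam <- overhead_camera(400)
  set.seed(2)
  pts <- cbind(runif(2500, -50, 50), runif(2500, -50, 50), 0)
  rownames(pts) <- paste0("P", seq_len(nrow(pts)))
  clean <- observe(cam, pts, rigid_identity(), 0)$points
  noisy <- observe(cam, pts, rigid_identity(), 1, seed = 9)$points
  dev <- noisy - clean
  expect_lt(abs(sd(dev) - 1), 0.05)
})

test_that("pose estimation is exact at zero noise over random poses", {
  cam <- overhead_camera(400)
  asm <- needle_assembly()
  set.seed(14)
  for (i in 1:40) {
    pose <- rigid_transform(rot_axis_angle(rnorm(3), runif(1, -0.5, 0.5)),
                            c(runif(2, -60, 60), runif(1, -40, 40)))
    est <- estimate_pose(observe(cam, asm$layout, pose, 0), asm$layout, cam)
    expect_true(est$converged)
    expect_lt(sqrt(sum((est$pose$t - pose$t)^2)), 1e-6)
    expect_lt(rotation_angle_between(est$pose, pose), 1e-6)
    expect_lt(est$reprojection_rms, 1e-8)
  }
})

test_that("planar four-point ambiguity resolves to the visible face", {
  cam <- overhead_camera(400)
  layout <- rbind(A = c(-25, -25, 0), B = c(25, -25, 0),
                  C = c(25, 25, 0), D = c(-25, 25, 0))
  set.seed(21)
  for (i in 1:10) {
    pose <- rigid_transform(rot_axis_angle(c(rnorm(2), 0), runif(1, 0.1, 0.45)),
                            c(runif(2, -40, 40), runif(1, -20, 20)))
    est <- estimate_pose(observe(cam, layout, pose, 0), layout, cam)
    expect_lt(est$reprojection_rms, 1e-8)    # reprojects exactly
    expect_lt(sqrt(sum((est$pose$t - pose$t)^2)), 1e-6)
    expect_lt(rotation_angle_between(est$pose, pose), 1e-6)
  }
})

test_that("degenerate observations are rejected", {
  cam <- overhead_camera(400)
  layout <- needle_assembly()$layout
  obs <- observe(cam, layout, rigid_identity(), 0)
  expect_error(estimate_pose(obs$points[1:3, ], layout[1:3, ], cam),
               "insufficient")
  line <- cbind(1:5, 1:5, 0)
  rownames(line) <- rownames(layout)
  expect_error(estimate_pose(obs, line, cam), "collinear|degenerate")
})

test_that("C++ refinement agrees with the pure-R oracle and the noise law", {
  cam <- overhead_camera(400)
  asm <- needle_assembly()
  tip_err <- function(sigma, n, use_oracle = FALSE) {
    vapply(seq_len(n), function(i) {
      pose <- rigid_transform(rot_axis_angle(rnorm(3), runif(1, -0.2, 0.2)),
                              c(runif(2, -30, 30), runif(1, -20, 20)))
      obs <- observe(cam, asm$layout, pose, sigma)
      est <- if (use_oracle) {
        oc <- compose_transforms(cam$pose, pose)  # init near truth
        fit <- endoguide:::refine_pose(oc$R, oc$t, asm$layout, obs$points,
                                       cam$f, cam$c)
        compose_transforms(invert_transform(cam$pose),
                           rigid_transform(endoguide:::project_so3(fit$R),
                                           fit$t))
      } else estimate_pose(obs, asm$layout, cam)$pose
      sqrt(sum((transform_points(est, asm$tip_offset) -
                  transform_points(pose, asm$tip_offset))^2))
    }, numeric(1))
  }
  # dual route: production C++ path vs pure-R numerical-Jacobian oracle on
  # identical noise realisations
  set.seed(31); impl <- tip_err(0.5, 150)
  set.seed(31); orac <- tip_err(0.5, 150, use_oracle = TRUE)
  expect_lt(abs(median(impl) - median(orac)) / median(orac), 0.1)
  # the geometry's information limit puts the median near 1.7 mm for this
  # layout (the independent oracle above computes the same value); assert
  # the few-mm regime rather than an optimistic closed-form guess
  expect_lt(median(impl), 2.5)
  expect_gt(median(impl), 0.5)

  # error grows linearly with pixel noise (R^2 > 0.9 over the sweep)
  set.seed(77)
  sig <- c(0.25, 0.5, 1, 2)
  means <- vapply(sig, function(s) mean(tip_err(s, 60)), numeric(1))
  fit <- lm(means ~ sig)
  expect_gt(summary(fit)$r.squared, 0.9)
  expect_true(all(diff(means) > 0))
})

test_that("warm-started estimation matches cold starts", {
  cam <- overhead_camera(400)
  asm <- needle_assembly()
  pose <- rigid_transform(rot_axis_angle(c(1, 1, 0), 0.15), c(12, 3, -8))
  obs <- observe(cam, asm$layout, pose, 0.5, seed = 4)
  cold <- estimate_pose(obs, asm$layout, cam)
  nearby <- rigid_transform(pose$R, pose$t + c(2, -2, 3))
  warm <- estimate_pose(obs, asm$layout, cam, init = nearby)
  expect_lt(sqrt(sum((cold$pose$t - warm$pose$t)^2)), 1e-5)
  expect_equal(cold$reprojection_rms, warm$reprojection_rms,
               tolerance = 1e-8)
})
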