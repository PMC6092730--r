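# geometry core: transforms, rigid registration, TRE

test_that("transform application handles the canonical cases", {
  expect_equal(transform_points(rigid_identity(), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(transform_points(rigid_transform(diag(3), c(1, 2, 3)),
                                c(0, 0, 0)), c(1, 2, 3))
  tf <- rigid_transform(rot_axis_angle(c(0, 0, 1), pi / 2))
  expect_equal(transform_points(tf, c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
})

test_that("rigid transforms preserve pairwise distances and compose/invert", {
  set.seed(11)
  pts <- matrix(rnorm(30, sd = 50), ncol = 3)
  d0 <- dist(pts)
  for (i in 1:20) {
    tf <- random_rigid_transform()
    expect_lt(max(abs(dist(transform_points(tf, pts)) - d0)), 1e-9)
    rt <- compose_transforms(invert_transform(tf), tf)
    expect_lt(max(abs(rt$R - diag(3))), 1e-9)
    expect_lt(max(abs(rt$t)), 1e-9)
  }
})

test_that("constructor rejects improper rotations", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
})

test_that("registration is exact on noiseless data", {
  src <- fiducial_set(quad_points(), frame = "CT")
  # identity
  r <- register_rigid(src, fiducial_set(quad_points(), frame = "TRACKER"))
  expect_lt(r$fre, 1e-9)
  expect_lt(max(abs(r$transform$R - diag(3))), 1e-9)
  # pure translation
  r <- register_rigid(src, fiducial_set(
    sweep(quad_points(), 2, c(5, -3, 2), `+`), frame = "TRACKER"))
  expect_equal(r$transform$t, c(5, -3, 2), tolerance = 1e-9)
  expect_lt(r$fre, 1e-9)
  # 30 degrees about (1,1,1)/sqrt(3) plus translation, 6 points
  set.seed(3)
  pts6 <- matrix(rnorm(18, sd = 60), ncol = 3)
  tf <- rigid_transform(rot_axis_angle(c(1, 1, 1), pi / 6), c(12, -7, 30))
  r <- register_rigid(fiducial_set(pts6),
                      fiducial_set(transform_points(tf, pts6),
                                   frame = "TRACKER"))
  expect_lt(max(abs(transform_points(r$transform, pts6) -
                      transform_points(tf, pts6))), 1e-9)
})

test_that("construct-apply-recover holds over 100 random rigid transforms", {
  set.seed(42)
  pts <- matrix(rnorm(24, sd = 80), ncol = 3)
  src <- fiducial_set(pts)
  for (i in 1:100) {
    tf <- random_rigid_transform()
    r <- register_rigid(src, fiducial_set(transform_points(tf, pts),
                                          frame = "TRACKER"))
    expect_lt(r$fre, 1e-9)
    expect_lt(max(abs(transform_points(r$transform, pts) -
                        transform_points(tf, pts))), 1e-9)
    expect_equal(det(r$transform$R), 1, tolerance = 1e-9)
  }
})

test_that("registration never returns a reflection", {
  # coplanar square plus a mirrored perturbation: the unconstrained optimum
  # of the Procrustes problem is a reflection, the constrained one is not
  sq <- rbind(c(0, 0, 0), c(50, 0, 0), c(50, 50, 0), c(0, 50, 0))
  mirrored <- sq %*% diag(c(1, 1, -1)) + matrix(rnorm(12, sd = 0.1), 4, 3)
  r <- register_rigid(fiducial_set(sq),
                      fiducial_set(mirrored, frame = "TRACKER"))
  expect_equal(det(r$transform$R), 1, tolerance = 1e-9)
})

test_that("degenerate and mismatched inputs are rejected", {
  line <- fiducial_set(cbind(1:5, 2 * (1:5), 3 * (1:5)))
  ok <- fiducial_set(quad_points()[1:3, ], labels = c("a", "b", "c"))
  expect_error(register_rigid(line, line), "collinear")
  relabeled <- fiducial_set(quad_points()[1:3, ], labels = c("b", "a", "c"),
                            frame = "TRACKER")
  expect_error(register_rigid(ok, relabeled), "correspondence")
  expect_error(fiducial_set(quad_points(), labels = c("a", "a", "b", "c")),
               "unique")
  expect_true(is_collinear(cbind(1:3, 1:3, 1:3)))
  expect_false(is_collinear(quad_points()))
  # planar sets are registrable (not degenerate)
  expect_false(is_collinear(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))))
})

test_that("mean FRE under isotropic noise matches the closed-form bias", {
  # The rigid fit absorbs 6 of the 3N noise degrees of freedom, so
  # E[sum residual^2] = (3N - 6) sigma^2 and E[FRE^2] = 3 sigma^2 (1 - 2/N)
  set.seed(99)
  N <- 12
  sigma <- 0.5
  pts <- matrix(rnorm(3 * N, sd = 100), ncol = 3)
  src <- fiducial_set(pts)
  fre <- replicate(1000, {
    register_rigid(src, fiducial_set(pts + matrix(rnorm(3 * N, 0, sigma),
                                                  ncol = 3),
                                     frame = "TRACKER"))$fre
  })
  expect_gt(mean(fre), 0.6)
  expect_lt(mean(fre), 1.1)
  expect_equal(mean(fre^2), 3 * sigma^2 * (1 - 2 / N), tolerance = 0.05)
})

test_that("TRE behaves: zero for equal maps, 3-4-5 offset, decreasing in N", {
  tf <- random_rigid_transform()
  dummy <- register_rigid(fiducial_set(quad_points()),
                          fiducial_set(transform_points(tf, quad_points()),
                                       frame = "TRACKER"))
  expect_lt(target_registration_error(dummy, tf, c(10, 20, 30)), 1e-9)
  off <- rigid_transform(diag(3), c(3, 0, 4))
  expect_equal(target_registration_error(off, rigid_identity(), c(7, 7, 7)),
               5)

  # Monte-Carlo: mean TRE non-increasing in fiducial count (fixed layout
  # family, fixed sigma).  600 reps per level (scaled down from the design's
  # illustrative 2000 for the test-time budget; the trend is far larger
  # than the Monte-Carlo error).
  set.seed(123)
  probe <- c(0, 0, -120)
  mean_tre <- vapply(c(4, 8, 16, 32), function(N) {
    ang <- 2 * pi * (seq_len(N) - 1) / N
    layout <- cbind(150 * cos(ang), 110 * sin(ang), 30 * sin(2 * ang))
    src <- fiducial_set(layout)
    mean(replicate(600, {
      noisy <- layout + matrix(rnorm(3 * N, 0, 0.5), ncol = 3)
      r <- register_rigid(src, fiducial_set(noisy, frame = "TRACKER"))
      target_registration_error(r, rigid_identity(), probe)
    }))
  }, numeric(1))
  expect_true(all(diff(mean_tre) < 0))
})

test_that("exhaustive correspondence matching recovers a permutation", {
  set.seed(5)
  pts <- matrix(rnorm(15, sd = 70), ncol = 3)
  src <- fiducial_set(pts)
  tf <- random_rigid_transform()
  perm <- c(3, 5, 1, 2, 4)
  dst <- fiducial_set(transform_points(tf, pts)[perm, ],
                      labels = paste0("U", 1:5), frame = "TRACKER")
  m <- match_fiducials(src, dst)
  expect_equal(m$permutation, order(perm))
  expect_lt(m$result$fre, 1e-9)
})

test_that("fiducial CSV and registration JSON round-trip", {
  fs <- fiducial_set(quad_points(), labels = c("A", "B", "C", "D"),
                     frame = "TRACKER")
  p <- withr::local_tempfile(fileext = ".csv")
  write_fiducials(fs, p)
  back <- read_fiducials(p)
  expect_equal(back$points, fs$points)
  expect_equal(back$frame, "TRACKER")

  tf <- random_rigid_transform()
  reg <- register_rigid(fiducial_set(quad_points()),
                        fiducial_set(transform_points(tf, quad_points()) +
                                       matrix(rnorm(12, 0, 0.2), 4, 3),
                                     frame = "TRACKER"))
  pj <- withr::local_tempfile(fileext = ".json")
  write_registration(reg, pj)
  back <- read_registration(pj)
  expect_equal(back$fre, reg$fre)
  expect_equal(back$transform$R, reg$transform$R, tolerance = 1e-12)
  expect_equal(unname(back$per_fiducial_residuals),
               unname(reg$per_fiducial_residuals))
})
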