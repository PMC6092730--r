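# segmentation and PCA marker-frame extraction

# brute-force 26-connectivity flood fill used as the independent oracle
flood_fill_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      k <- (cur - 1L) %/% (d[1] * d[2])
      j <- ((cur - 1L) %/% d[1]) %% d[2]
      i <- (cur - 1L) %% d[1]
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] ||
            kk < 0 || kk >= d[3]) next
        nb <- kk * d[1] * d[2] + jj * d[1] + ii + 1L
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

cube_volume <- function(gap) {
  # two 3x3x3 intensity-3000 cubes, separated by `gap` background voxels
  a <- array(0, c(12 + gap, 9, 9))
  a[2:4, 4:6, 4:6] <- 3000
  a[(5 + gap):(7 + gap), 4:6, 4:6] <- 3000
  voxel_volume(a, c(1, 1, 1))
}

test_that("connected components match the brute-force oracle", {
  for (gap in c(0, 1, 3)) {
    vol <- cube_volume(gap)
    lm <- segment(vol, 2000, 4000, min_size = 1)
    oracle <- flood_fill_oracle(vol$data >= 2000 & vol$data <= 4000)
    expect_equal(n_components(lm), max(oracle))
    # identical partition (up to label naming)
    for (l in seq_len(n_components(lm)))
      expect_equal(length(unique(oracle[lm$labels == l])), 1L)
  }
  expect_equal(n_components(segment(cube_volume(1), 2000, 4000)), 2)
  expect_equal(n_components(segment(cube_volume(0), 2000, 4000)), 1)
})

test_that("empty band and degenerate inputs behave", {
  vol <- voxelize(empty_scene(tissue = FALSE), spacing = 2)
  b <- intensity_band("fiducial")
  lm <- segment(vol, b[1], b[2])
  expect_equal(n_components(lm), 0)
  expect_error(segment(vol, 10, 10), "threshold_low")
  expect_error(target_centre(lm, 1), "absent")
  expect_error(extract_marker_frame(lm, 3), "absent")
})

test_that("labels are ordered by decreasing size and min_size filters", {
  a <- array(0, c(20, 8, 8))
  a[2:11, 2:4, 2:4] <- 3000   # 90 voxels
  a[14:15, 2:3, 2:3] <- 3000  # 8 voxels
  a[18, 6, 6] <- 3000         # 1 voxel speck
  vol <- voxel_volume(a, c(1, 1, 1))
  lm <- segment(vol, 2000, 4000, min_size = 4)
  expect_equal(n_components(lm), 2)
  expect_equal(lm$sizes, c(90, 8))
  lm1 <- segment(vol, 2000, 4000, min_size = 1)
  expect_equal(n_components(lm1), 3)
  expect_equal(lm1$sizes, c(90, 8, 1))
})

test_that("axis-aligned slab yields exact centroid and vertical normal", {
  sc <- mini_scene(with_target = FALSE, tilt_deg = 0)  # slab at (10, 20, 30)
  vol <- voxelize(sc, spacing = 1)
  b <- intensity_band("fiducial")
  lm <- segment(vol, b[1], b[2])
  expect_equal(n_components(lm), 1)
  mf <- extract_marker_frame(lm, 1, interior_point = c(0, 0, 0))
  expect_lt(max(abs(mf$centroid - c(10, 20, 30))), 0.5)
  ang <- acos(min(1, abs(sum(mf$axes[, 3] * c(0, 0, 1)))))
  expect_lt(ang, 2 * pi / 180)
  expect_true(all(diff(mf$eigenvalues) <= 0))
  expect_lt(max(abs(crossprod(mf$axes) - diag(3))), 1e-9)
  # normal sign: away from the interior point
  expect_gt(sum(mf$axes[, 3] * (mf$centroid - c(0, 0, 0))), 0)
})

test_that("tilted slab normal is recovered within 2 degrees", {
  for (tilt in c(20, 45)) {
    sc <- mini_scene(with_target = FALSE, tilt_deg = tilt)
    vol <- voxelize(sc, spacing = 1)
    b <- intensity_band("fiducial")
    lm <- segment(vol, b[1], b[2])
    mf <- extract_marker_frame(lm, 1, interior_point = c(0, 0, 0))
    truth <- c(sin(tilt * pi / 180), 0, cos(tilt * pi / 180))
    ang <- acos(min(1, abs(sum(mf$axes[, 3] * truth))))
    expect_lt(ang, 2 * pi / 180)
    expect_lt(max(abs(mf$centroid - c(10, 20, 30))), sqrt(3))
  }
})

test_that("target centroids hit known centres", {
  # single-voxel component: centroid is exactly the voxel centre
  a <- array(0, c(9, 9, 9))
  a[4, 6, 2] <- 300
  vol <- voxel_volume(a, c(1, 1, 1), origin = c(-10, 5, 3))
  lm <- segment(vol, 200, 400, min_size = 1)
  expect_equal(unname(target_centre(lm, 1)),
               c(-10 + 3, 5 + 5, 3 + 1))
  # voxelized sphere: centroid within sqrt(3) * spacing of the true centre
  sc <- mini_scene(with_fiducial = FALSE)
  vol <- voxelize(sc, spacing = 1)
  tb <- intensity_band("target")
  lm <- segment(vol, tb[1], tb[2])
  expect_lt(sqrt(sum((target_centre(lm, 1) - c(0, 0, 0))^2)), sqrt(3))
})

test_that("PCA frames are equivariant under scene rotation", {
  base <- mini_scene(with_target = FALSE, tilt_deg = 25)
  ang <- 30 * pi / 180
  R <- rot_axis_angle(c(0, 0, 1), ang)
  f0 <- base$fiducials[[1]]
  rot <- base
  rot$fiducials <- list(square_fiducial(as.numeric(R %*% f0$centre),
                                        as.numeric(R %*% f0$normal),
                                        as.numeric(R %*% f0$axis1),
                                        label = "F1"))
  b <- intensity_band("fiducial")
  get_frame <- function(sc) {
    vol <- voxelize(sc, spacing = 1)
    extract_marker_frame(segment(vol, b[1], b[2]), 1,
                         interior_point = c(0, 0, 0))
  }
  mf0 <- get_frame(base)
  mf1 <- get_frame(rot)
  expect_lt(sqrt(sum((mf1$centroid - as.numeric(R %*% mf0$centroid))^2)),
            sqrt(3))
  ang_err <- acos(min(1, abs(sum(mf1$axes[, 3] * (R %*% mf0$axes[, 3])))))
  expect_lt(ang_err, 3 * pi / 180)
})

test_that("scenario fiducial recovery is complete and sub-voxel accurate", {
  for (scn in c("porcine", "cadaver")) {
    ps <- cached_pscene(scn)
    truth <- scene_fiducial_centres(ps)
    expect_equal(ps$fiducial_count, nrow(truth$points))
    errs <- sqrt(rowSums((ps$ct_fiducials$points -
                            truth$points[ps$ct_fiducials$labels, ])^2))
    expect_lt(sqrt(mean(errs^2)), 0.6)
  }
})
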