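#' Pinhole camera model
#'
#' Intrinsics plus a world-to-camera pose.  Defaults stand in for a tablet's
#' 12-megapixel back camera: focal length 1500 px, 4000 x 3000 px image,
#' principal point at the image centre.  The camera frame has +z pointing
#' into the scene.
#'
#' @param focal_px focal length in pixels (> 0).
#' @param image_px length-2 image size `c(width, height)` in pixels.
#' @param principal_px principal point (defaults to the image centre); must
#'   lie inside the image.
#' @param pose `rigid_transform` mapping world to camera coordinates.
#' @return A `camera_model`.
#' @export
camera_model <- function(focal_px = 1500, image_px = c(4000, 3000),
                         principal_px = image_px / 2,
                         pose = rigid_identity()) {
  stopifnot(focal_px > 0, length(image_px) == 2L,
            inherits(pose, "rigid_transform"))
  if (any(principal_px < 0) || any(principal_px > image_px))
    stop("principal point must lie inside the image bounds")
  structure(list(f = focal_px, image = as.numeric(image_px),
                 c = as.numeric(principal_px), pose = pose),
            class = "camera_model")
}

#' Camera looking straight down at a scene from above
#'
#' Places the camera on the world +z axis at `distance` mm above `look_at`,
#' with the optical axis along world -z (the tabletop geometry of the
#' experiments; the tablet is on a tripod above the body).
#'
#' @param distance camera-to-scene distance along z (mm).
#' @param look_at world point under the camera (mm).
#' @param ... passed to [camera_model()].
#' @return A `camera_model`.
#' @export
overhead_camera <- function(distance = 400, look_at = c(0, 0, 0), ...) {
  Rwc <- diag(c(1, -1, -1))  # 180 deg about x: world -z becomes camera +z
  centre <- look_at + c(0, 0, distance)
  camera_model(pose = rigid_transform(Rwc, as.numeric(-Rwc %*% centre)), ...)
}

#' Perspective projection
#'
#' `u = f x/z + cx`, `v = f y/z + cy` after the world-to-camera transform.
#'
#' @param camera a [camera_model()].
#' @param pts_world N x 3 world points (mm); all must have positive depth.
#' @return N x 2 matrix of pixel coordinates.
#' @export
project <- function(camera, pts_world) {
  if (is.null(dim(pts_world))) pts_world <- matrix(pts_world, ncol = 3)
  pc <- transform_points(camera$pose, pts_world)
  if (any(pc[, 3] <= 0))
    stop("behind-camera error: point with non-positive depth")
  cbind(camera$f * pc[, 1] / pc[, 3] + camera$c[1],
        camera$f * pc[, 2] / pc[, 3] + camera$c[2])
}

#' Simulated marker detection
#'
#' Projects an object-frame marker layout posed in the world and adds
#' independent Gaussian pixel noise.  Detection is simulated rather than
#' computed from rendered pixels: the physical system's corner detector runs
#' inside a commercial AR toolkit, and a noise parameter keeps the accuracy
#' chain testable while isolating the pose mathematics.
#'
#' @param camera a [camera_model()].
#' @param layout N x 3 labelled object-frame points (mm), rownames = labels.
#' @param true_pose `rigid_transform`, object frame to world.
#' @param sigma_px Gaussian pixel noise SD (>= 0).
#' @param seed optional integer; when given, the observation is an isolated
#'   deterministic draw, otherwise the current RNG stream is used.
#' @return An `observation_2d`: list with `points` (N x 2 pixels, labelled)
#'   and `sigma_px`.
#' @export
observe <- function(camera, layout, true_pose, sigma_px = 0, seed = NULL) {
  stopifnot(sigma_px >= 0)
  layout <- as.matrix(layout)
  pts_w <- transform_points(true_pose, layout)
  uv <- project(camera, pts_w)
  add_noise <- function() {
    if (sigma_px > 0) uv + matrix(stats::rnorm(length(uv), 0, sigma_px),
                                  ncol = 2) else uv
  }
  uv <- if (is.null(seed)) add_noise() else with_local_seed(seed, add_noise())
  rownames(uv) <- rownames(layout)
  structure(list(points = uv, sigma_px = sigma_px), class = "observation_2d")
}

# --- pose estimation ------------------------------------------------------

# residual vector (pixels) of an object->camera pose, given normalized
# layout and observation; pose parametrized by the reference rotation R0
# times exp([w]x) and translation t
pose_residuals <- function(par, R0, layout, uv, f, cc) {
  R <- R0 %*% rot_exp(par[1:3])
  pc <- sweep(layout %*% t(R), 2, par[4:6], `+`)
  z <- pc[, 3]
  if (any(z <= 1e-9)) return(rep(1e6, 2 * nrow(layout)))
  c(f * pc[, 1] / z + cc[1] - uv[, 1],
    f * pc[, 2] / z + cc[2] - uv[, 2])
}

rot_exp <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew3(w))
  rot_axis_angle(w, th)
}

skew3 <- function(a) matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)

# Reference Levenberg-Marquardt over 6 pose parameters with numerical
# Jacobian.  The production path is the C++ implementation with the
# analytic Jacobian (src/pose.cpp); this pure-R version is retained as the
# independent oracle the tests compare against.
refine_pose <- function(R_init, t_init, layout, uv, f, cc,
                        max_iter = 100, reltol = 1e-10) {
  par <- c(0, 0, 0, t_init)
  R0 <- R_init
  lambda <- 1e-3
  r <- pose_residuals(par, R0, layout, uv, f, cc)
  cost <- sum(r^2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # fold accumulated rotation into R0 to keep w small
    R0 <- project_so3(R0 %*% rot_exp(par[1:3]))
    par[1:3] <- 0
    J <- matrix(0, length(r), 6)
    h <- 1e-6
    for (p in 1:6) {
      dp <- par
      dp[p] <- dp[p] + h
      J[, p] <- (pose_residuals(dp, R0, layout, uv, f, cc) - r) / h
    }
    A <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    for (k in 1:10) {
      step <- tryCatch(solve(A + lambda * diag(diag(A) + 1e-12), g),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- par - as.numeric(step)
      rc <- pose_residuals(cand, R0, layout, uv, f, cc)
      cc_cost <- sum(rc^2)
      if (cc_cost < cost) {
        rel <- (cost - cc_cost) / max(cost, 1e-300)
        par <- cand; r <- rc; cost <- cc_cost
        lambda <- max(lambda / 10, 1e-12)
        improved <- TRUE
        if (rel < reltol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  R <- project_so3(R0 %*% rot_exp(par[1:3]))
  list(R = R, t = par[4:6], rms = sqrt(cost / nrow(layout) / 2),
       converged = converged)
}

# Homography-based initial pose for (near-)planar layouts: project layout
# onto its best-fit plane, estimate the plane-to-image homography (DLT with
# Hartley normalisation) and decompose.  Returns the two candidate poses of
# the planar ambiguity.
homography_init <- function(layout, uv, f, cc) {
  ctr <- colMeans(layout)
  e <- eigen(stats::cov(layout), symmetric = TRUE)
  B <- e$vectors                      # columns; third = plane normal
  if (det(B) < 0) B[, 3] <- -B[, 3]
  P2 <- sweep(layout, 2, ctr) %*% B   # plane coords (x, y, ~0)
  x <- P2[, 1]; y <- P2[, 2]
  u <- (uv[, 1] - cc[1]) / f
  v <- (uv[, 2] - cc[2]) / f
  n <- length(x)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    A[2 * i - 1, ] <- c(x[i], y[i], 1, 0, 0, 0, -u[i] * x[i], -u[i] * y[i], -u[i])
    A[2 * i, ]     <- c(0, 0, 0, x[i], y[i], 1, -v[i] * x[i], -v[i] * y[i], -v[i])
  }
  H <- matrix(svd(A, nv = 9)$v[, 9], 3, 3, byrow = TRUE)
  out <- list()
  for (sgn in c(1, -1)) {
    Hs <- sgn * H
    h1 <- Hs[, 1]; h2 <- Hs[, 2]
    lam <- 2 / (sqrt(sum(h1^2)) + sqrt(sum(h2^2)))
    r1 <- lam * h1; r2 <- lam * h2
    R <- cbind(r1, r2, cross3(r1, r2))
    R <- project_so3(R)
    tt <- lam * Hs[, 3]
    if (tt[3] <= 0) next                   # object must be in front
    # object->camera: account for the plane basis and centring
    Rfull <- R %*% t(B)
    tfull <- tt - as.numeric(Rfull %*% ctr)
    out[[length(out) + 1]] <- list(R = Rfull, t = tfull)
  }
  out
}

#' Estimate an object pose from a 2-D observation
#'
#' Minimises the sum of squared reprojection errors over the rigid
#' object-to-camera pose by Levenberg-Marquardt, then returns the pose in
#' the world frame.  Initialisation is a plane-to-image homography
#' decomposition (the layout is projected to its best-fit plane first, so
#' near-planar clusters such as the handle face work too); both solutions of
#' the two-fold planar ambiguity are refined, and the winner is the one
#' whose marker normal faces the camera, ties broken by lower reprojection
#' RMS.  Passing `init` (e.g. the previous tracking step's estimate) skips
#' initialisation.
#'
#' @param obs an [observe()] result (or bare N x 2 pixel matrix with
#'   rownames).
#' @param layout N x 3 object-frame points with matching rownames; N >= 4,
#'   non-collinear.
#' @param camera a [camera_model()].
#' @param init optional `rigid_transform` (object to world) warm start.
#' @param max_iter,reltol Levenberg-Marquardt stopping controls.
#' @return A `pose_estimate`: list with `pose` (`rigid_transform`, object to
#'   world), `reprojection_rms` (pixels), `converged` flag.
#' @export
estimate_pose <- function(obs, layout, camera, init = NULL,
                          max_iter = 100, reltol = 1e-10) {
  uv <- if (inherits(obs, "observation_2d")) obs$points else as.matrix(obs)
  layout <- as.matrix(layout)
  if (nrow(uv) < 4) stop("insufficient data: pose estimation needs >= 4 points")
  if (!is.null(rownames(uv)) && !is.null(rownames(layout))) {
    if (!setequal(rownames(uv), rownames(layout)))
      stop("correspondence error: observation and layout labels differ")
    uv <- uv[rownames(layout), , drop = FALSE]
  }
  if (is_collinear(layout)) stop("degenerate layout: points are collinear")
  f <- camera$f; cc <- camera$c

  cands <- list()
  if (!is.null(init)) {
    oc <- compose_transforms(camera$pose, init)   # object -> camera
    cands <- list(list(R = oc$R, t = oc$t))
  } else {
    cands <- homography_init(layout, uv, f, cc)
    if (!length(cands)) {
      # fallback: overhead guess at a depth matched to the apparent scale
      spread3 <- sqrt(mean(rowSums(sweep(layout, 2, colMeans(layout))^2)))
      spread2 <- sqrt(mean(rowSums(sweep(uv, 2, colMeans(uv))^2)))
      z0 <- f * spread3 / max(spread2, 1e-6)
      cands <- list(list(R = diag(3), t = c(0, 0, z0)))
    }
  }
  best <- NULL
  best_key <- NULL
  for (cand in cands) {
    fit <- .refine_pose_lm(cand$R, cand$t, layout, uv, f, cc, max_iter, reltol)
    fit$R <- project_so3(fit$R)
    # visibility rule: the layout's best-fit-plane normal, mapped to camera
    # coordinates, should face the camera (negative z)
    nrm_obj <- eigen(stats::cov(layout), symmetric = TRUE)$vectors[, 3]
    if (nrm_obj[3] < 0) nrm_obj <- -nrm_obj  # marker face is +z in object frame
    nrm_cam <- as.numeric(fit$R %*% nrm_obj)
    ctr_cam <- as.numeric(fit$R %*% colMeans(layout) + fit$t)
    facing <- sum(nrm_cam * ctr_cam) < 0   # normal against the viewing ray
    key <- c(!facing, fit$rms)             # prefer facing, then lower RMS
    if (is.null(best) || key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2] - 1e-15)) {
      best <- fit
      best_key <- key
    }
  }
  pose_cam <- rigid_transform(best$R, best$t)                 # object->camera
  pose_world <- compose_transforms(invert_transform(camera$pose), pose_cam)
  structure(list(pose = pose_world, reprojection_rms = best$rms,
                 converged = best$converged),
            class = "pose_estimate")
}

#' @export
print.pose_estimate <- function(x, ...) {
  cat("<pose_estimate> reprojection RMS:",
      format(signif(x$reprojection_rms, 4)), "px; converged:",
      x$converged, "\n")
  print(x$pose)
  invisible(x)
}
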