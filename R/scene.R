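#' @useDynLib endoguide, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Seed hygiene: builders are deterministic in their `seed` argument without
# clobbering the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---------------------------------------------------------------------------
# Body envelope: a superellipsoid |x/a|^p + |y/b|^p + |z/c|^p = 1.  A smooth
# closed surface is all the fiducial-on-skin / target-at-depth semantics
# need; no anatomical mesh is attempted.

superellipsoid <- function(semi_axes, exponent = 3, centre = c(0, 0, 0)) {
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0), exponent >= 2)
  structure(list(semi_axes = as.numeric(semi_axes), exponent = exponent,
                 centre = as.numeric(centre)), class = "superellipsoid")
}

envelope_value <- function(env, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  rel <- sweep(pts, 2, env$centre)
  rel <- sweep(abs(rel), 2, env$semi_axes, `/`)
  rowSums(rel^env$exponent)
}

envelope_inside <- function(env, pts, margin = 0) {
  # margin > 0 demands the point be at least that far (approximately) inside
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  if (margin > 0) {
    # shrink the envelope by `margin` along each semi-axis (conservative)
    env <- superellipsoid(pmax(env$semi_axes - margin, 1e-6), env$exponent,
                          env$centre)
  }
  envelope_value(env, pts) <= 1
}

# surface point along a direction from the centre
envelope_surface_point <- function(env, direction) {
  d <- as.numeric(direction)
  s <- (sum((abs(d) / env$semi_axes)^env$exponent))^(-1 / env$exponent)
  env$centre + s * d
}

# z of the upper surface above (x, y); NA outside the footprint
envelope_top_z <- function(env, x, y) {
  rx <- abs(x - env$centre[1]) / env$semi_axes[1]
  ry <- abs(y - env$centre[2]) / env$semi_axes[2]
  rem <- 1 - rx^env$exponent - ry^env$exponent
  ifelse(rem <= 0, NA_real_,
         env$centre[3] + env$semi_axes[3] * rem^(1 / env$exponent))
}

# outward unit normal (gradient of the implicit function)
envelope_normal <- function(env, pt) {
  rel <- (pt - env$centre) / env$semi_axes
  g <- env$exponent * sign(rel) * abs(rel)^(env$exponent - 1) / env$semi_axes
  g / sqrt(sum(g^2))
}

# ---------------------------------------------------------------------------
# Scene primitives

#' Scene primitives
#'
#' Constructors for the geometric objects a scene is made of: radiopaque
#' square skin fiducials, cylindrical bar targets, small implanted point
#' targets (2 x 1 mm ellipsoids), spherical lesions, and the tracked needle
#' assembly (handle marker cluster plus a 170 mm tip offset).
#'
#' @param centre,endpoint_a,endpoint_b length-3 positions (mm).
#' @param normal,in_plane unit vectors defining the fiducial plane.
#' @param edge,thickness,radius,diameter sizes in mm.
#' @param extent ellipsoid axis lengths (mm), default `c(2, 1, 1)`.
#' @param label identifier string.
#' @name scene-primitives
NULL

#' @rdname scene-primitives
#' @export
square_fiducial <- function(centre, normal, in_plane, edge = 35, thickness = 2,
                            label = NULL) {
  normal <- normal / sqrt(sum(normal^2))
  in_plane <- in_plane - sum(in_plane * normal) * normal
  in_plane <- in_plane / sqrt(sum(in_plane^2))
  if (abs(sum(normal * in_plane)) >= 1e-9)
    stop("fiducial normal and in-plane axis must be orthogonal")
  stopifnot(edge > 0, thickness > 0)
  structure(list(centre = as.numeric(centre), normal = normal,
                 axis1 = in_plane, axis2 = cross3(normal, in_plane),
                 edge = edge, thickness = thickness, label = label),
            class = "square_fiducial")
}

#' @rdname scene-primitives
#' @export
bar_target <- function(endpoint_a, endpoint_b, radius, label) {
  len <- sqrt(sum((endpoint_b - endpoint_a)^2))
  stopifnot(len > 0, radius > 0)
  structure(list(endpoint_a = as.numeric(endpoint_a),
                 endpoint_b = as.numeric(endpoint_b),
                 radius = radius, length = len, label = label,
                 centre = (endpoint_a + endpoint_b) / 2),
            class = c("bar_target", "scene_target"))
}

#' @rdname scene-primitives
#' @export
point_target <- function(centre, extent = c(2, 1, 1), label) {
  stopifnot(all(extent > 0))
  structure(list(centre = as.numeric(centre), extent = as.numeric(extent),
                 label = label),
            class = c("point_target", "scene_target"))
}

#' @rdname scene-primitives
#' @export
sphere_lesion <- function(centre, diameter, label) {
  stopifnot(diameter > 0)
  structure(list(centre = as.numeric(centre), diameter = diameter,
                 label = label),
            class = c("sphere_lesion", "scene_target"))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Needle assembly: handle marker cluster plus tip offset
#'
#' The default handle layout is four markers at the corners of a 40 x 40 mm
#' square on the handle face plus one marker 20 mm above the centre
#' (non-coplanar, which stabilises camera pose estimation), and the tip
#' sits 170 mm from the handle origin along the handle -z axis (a 17 cm
#' needle rigidly attached to the handle).
#'
#' @param layout N x 3 matrix (N >= 4) of marker positions in the handle
#'   frame (mm), rownames used as labels.
#' @param tip_offset length-3 vector, handle frame; its norm must be 170 mm.
#' @return A `needle_assembly`.
#' @export
needle_assembly <- function(layout = NULL, tip_offset = c(0, 0, -170)) {
  if (is.null(layout)) {
    layout <- rbind(H1 = c(-20, -20, 0), H2 = c(20, -20, 0),
                    H3 = c(20, 20, 0), H4 = c(-20, 20, 0),
                    H5 = c(0, 0, 20))
  }
  layout <- as.matrix(layout)
  stopifnot(ncol(layout) == 3L, nrow(layout) >= 4L)
  if (is.null(rownames(layout))) rownames(layout) <- paste0("H", seq_len(nrow(layout)))
  if (is_collinear(layout)) stop("handle marker layout is collinear")
  if (abs(sqrt(sum(tip_offset^2)) - 170) >= 1e-9)
    stop("tip offset must have norm 170 mm (17 cm needle)")
  structure(list(layout = layout, tip_offset = as.numeric(tip_offset)),
            class = "needle_assembly")
}

# ---------------------------------------------------------------------------
# Fiducial placement: quasi-uniform sunflower lattice over the upper surface
# with a small seeded jitter, each sticker conforming to the local surface
# (centre on the skin, normal = outward surface normal).

# Quasi-uniform jittered grid over the upper-surface footprint.  A grid
# (rather than a spiral lattice) guarantees sticker clearance: 35 mm squares
# merge under 26-connectivity when centres come within ~50 mm, so the grid
# pitch must stay comfortably above that.
place_surface_fiducials <- function(env, n, radial_fraction = 0.82,
                                    jitter_mm = 4, min_sep_mm = 48) {
  a <- env$semi_axes[1] * radial_fraction * 0.93
  b <- env$semi_axes[2] * radial_fraction * 0.93
  nc <- ceiling(sqrt(n * a / b))
  nr <- ceiling(n / nc)
  gx <- if (nc > 1) seq(-a, a, length.out = nc) else 0
  gy <- if (nr > 1) seq(-b, b, length.out = nr) else 0
  cells <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  placed <- matrix(NA_real_, n, 3)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    # re-draw the jitter until the sticker clears its placed neighbours
    for (attempt in 1:25) {
      jit <- if (attempt < 25) stats::runif(2, -jitter_mm, jitter_mm) else c(0, 0)
      x <- env$centre[1] + cells$x[k] + jit[1]
      y <- env$centre[2] + cells$y[k] + jit[2]
      z <- envelope_top_z(env, x, y)
      if (is.na(z)) next
      if (k > 1) {
        d2 <- min(rowSums(sweep(placed[seq_len(k - 1), , drop = FALSE], 2,
                                c(x, y, z))^2))
        if (d2 < min_sep_mm^2) next
      }
      break
    }
    if (is.na(z)) stop("construction error: cannot place fiducial ", k,
                       " on the surface")
    ctr <- c(x, y, z)
    placed[k, ] <- ctr
    nrm <- envelope_normal(env, ctr)
    ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax1 <- ref - sum(ref * nrm) * nrm
    ax1 <- ax1 / sqrt(sum(ax1^2))
    out[[k]] <- square_fiducial(ctr, nrm, ax1, label = paste0("F", k))
  }
  if (min(stats::dist(placed)) < 44)
    stop("construction error: fiducials too crowded for this envelope")
  out
}

# ---------------------------------------------------------------------------
# Reference pairwise bar-centre distances for the trunk phantom (mm), as
# previously measured on the physical phantom.  These printed values are
# mutually inconsistent as Euclidean distances (d35 = 156.0 exceeds
# d34 + d45 = 152.9), so an exact embedding is impossible; the builder
# finds the least-squares 3-D embedding and records the residuals.

#' Reference bar-centre distance table of the trunk phantom
#'
#' Ten previously measured pairwise distances (mm) between the geometric
#' centres of the five bars, with both the physical ("real") measurement and
#' the earlier augmented-reality ("virtual") measurement.  Shipped as
#' `inst/extdata/anthro_reference_distances.csv`.
#'
#' @return data.frame with columns `pair`, `real_mm`, `virtual_mm`, `abs_diff_mm`.
#' @export
reference_bar_distances <- function() {
  path <- system.file("extdata", "anthro_reference_distances.csv",
                      package = "endoguide", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

reference_distance_matrix <- function() {
  d <- reference_bar_distances()
  m <- matrix(0, 5, 5, dimnames = list(paste0("Bar", 1:5), paste0("Bar", 1:5)))
  for (i in seq_len(nrow(d))) {
    ij <- as.integer(strsplit(sub("Bar", "", d$pair[i]), "-Bar")[[1]])
    m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- d$real_mm[i]
  }
  m
}

# Least-squares 3-D embedding of a distance matrix: classical MDS start,
# then quasi-Newton refinement of the raw stress sum((dij - |xi-xj|)^2).
embed_distances <- function(D) {
  n <- nrow(D)
  X0 <- stats::cmdscale(stats::as.dist(D), k = 3)
  if (ncol(X0) < 3) X0 <- cbind(X0, matrix(0, n, 3 - ncol(X0)))
  stress <- function(par) {
    X <- matrix(par, n, 3)
    dd <- as.matrix(stats::dist(X))
    sum((dd[upper.tri(dd)] - D[upper.tri(D)])^2)
  }
  opt <- stats::optim(as.numeric(X0), stress, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  X <- matrix(opt$par, n, 3)
  X <- sweep(X, 2, colMeans(X))
  dd <- as.matrix(stats::dist(X))
  resid <- dd[upper.tri(dd)] - D[upper.tri(D)]
  list(coords = X, residuals = resid, rms = sqrt(mean(resid^2)))
}

# ---------------------------------------------------------------------------
# Scene container

new_scene <- function(scenario, envelope, fiducials, targets, needle,
                      patient_pose, entry_points, seed, extra = list()) {
  centres <- t(vapply(fiducials, `[[`, numeric(3), "centre"))
  on_surface <- abs(envelope_value(envelope, centres) - 1) # implicit value
  # centres are constructed on the surface; sanity check within 1 mm scaled
  structure(c(list(scenario = scenario, envelope = envelope,
                   fiducials = fiducials, targets = targets, needle = needle,
                   patient_pose = patient_pose, entry_points = entry_points,
                   seed = seed), extra),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("<scene_spec> scenario:", x$scenario, "\n",
      " fiducials:", length(x$fiducials),
      " targets:", length(x$targets),
      " envelope semi-axes (mm):", paste(x$envelope$semi_axes, collapse = " x "),
      "\n")
  invisible(x)
}

#' Ground-truth marker and target positions of a scene
#'
#' @param scene a `scene_spec`.
#' @return `scene_fiducial_centres()`: a CT-frame [fiducial_set()] of the true
#'   fiducial centres; `scene_target_centres()`: named matrix of true target
#'   centres (CT frame, mm).
#' @export
scene_fiducial_centres <- function(scene) {
  pts <- t(vapply(scene$fiducials, `[[`, numeric(3), "centre"))
  labs <- vapply(scene$fiducials, `[[`, character(1), "label")
  fiducial_set(pts, labs, frame = "CT")
}

#' @rdname scene_fiducial_centres
#' @export
scene_target_centres <- function(scene) {
  pts <- t(vapply(scene$targets, `[[`, numeric(3), "centre"))
  rownames(pts) <- vapply(scene$targets, `[[`, character(1), "label")
  pts
}

default_patient_pose <- function() {
  rigid_transform(rot_axis_angle(c(0, 0, 1), 10 * pi / 180) %*%
                    rot_axis_angle(c(1, 0, 0), 3 * pi / 180),
                  c(5, 8, 2))
}

# entry point on the upper surface at an exact straight-line distance
# `depth` from `centre`: walk outward in x until the chord length matches.
surface_entry_at_depth <- function(env, centre, depth) {
  f <- function(dx) {
    x <- centre[1] + dx
    z <- envelope_top_z(env, x, centre[2])
    if (is.na(z)) return(NA_real_)
    sqrt(dx^2 + (z - centre[3])^2) - depth
  }
  v0 <- f(0)
  if (is.na(v0)) stop("target centre is not under the upper surface")
  if (v0 > 0) stop("construction error: depth ", depth,
                   " mm is shallower than the vertical skin distance")
  hi <- 0
  repeat {
    hi <- hi + 10
    vh <- f(hi)
    if (is.na(vh)) stop("construction error: no surface entry at depth ",
                        depth, " mm")
    if (vh >= 0) break
    if (hi > 4 * depth) stop("construction error: no surface entry at depth ",
                             depth, " mm")
  }
  dx <- stats::uniroot(f, c(hi - 10, hi), tol = 1e-10)$root
  x <- centre[1] + dx
  c(x, centre[2], envelope_top_z(env, x, centre[2]))
}

# Snap a target centre to the integer-mm lattice: implanted 2x1 mm markers
# span only 1-3 voxels, so the generator states grid-aligned centres as part
# of the synthetic world (sub-voxel placement of such markers is pure
# aliasing).  x,y are rounded; z is snapped upward from (skin - depth) so the
# vertical skin distance never exceeds the stated depth and the exact-depth
# entry point exists on the surface.
snap_target_centre <- function(env, xy, depth) {
  xy <- round(xy)
  ztop <- envelope_top_z(env, xy[1], xy[2])
  if (is.na(ztop)) stop("construction error: entry (x,y) off the body")
  c(xy[1], xy[2], ceiling(ztop - depth))
}

# ---------------------------------------------------------------------------
# Scenario builders

#' Build the anthropomorphic trunk-phantom scene
#'
#' A 500 x 340 x 270 mm trunk-shaped superellipsoid containing five
#' cylindrical bar targets (two 160 mm long, 30 mm diameter; three longer,
#' 20 mm diameter) and thirty 35 x 35 mm radiopaque squares on the upper
#' surface.  Bar geometric centres are placed by least-squares 3-D embedding
#' of the ten reference pairwise distances (classical multidimensional
#' scaling plus quasi-Newton refinement); since the printed distances are
#' not exactly Euclidean the embedding residuals are recorded in
#' `scene$embedding$residuals`.
#'
#' @param config optional list overriding `envelope_mm` (default
#'   `c(500, 340, 270)` full widths), `n_fiducials` (30), `n_bars` (5),
#'   `bar_lengths`, `bar_radii`.
#' @param seed integer; the scene is deterministic given `config` + `seed`.
#' @return A `scene_spec`.
#' @export
build_anthropomorphic_scene <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(envelope_mm = c(500, 340, 270),
                                n_fiducials = 30, n_bars = 5,
                                bar_lengths = c(160, 160, 450, 300, 200),
                                bar_radii = c(15, 15, 10, 10, 10)),
                           config)
  if (cfg$n_bars < 1) stop("construction error: at least one bar required")
  if (cfg$n_bars != 5)
    stop("construction error: the reference distance table defines 5 bars")
  env <- superellipsoid(cfg$envelope_mm / 2, exponent = 4)
  with_local_seed(seed, {
    emb <- embed_distances(reference_distance_matrix())
    X <- emb$coords
    # orient: spread in the y-z cross-section, least variance along x so the
    # long bars (axis along x) stay inside the envelope
    pc <- eigen(stats::cov(X), symmetric = TRUE)
    Rmap <- pc$vectors[, c(3, 1, 2)]  # least variance -> x
    if (det(Rmap) < 0) Rmap[, 3] <- -Rmap[, 3]
    X <- X %*% Rmap
    # longest bars go to the centres with the most axial clearance, i.e.
    # the least envelope crowding in the y-z cross-section
    X <- round(X)  # lattice-aligned centres: voxelized bars stay symmetric
    crowd <- rowSums(sweep(abs(X[, 2:3, drop = FALSE]), 2,
                           env$semi_axes[2:3], `/`)^env$exponent)
    ord <- order(crowd)
    lengths <- numeric(5); radii <- numeric(5)
    by_len <- order(cfg$bar_lengths, decreasing = TRUE)
    lengths[ord] <- cfg$bar_lengths[by_len]
    radii[ord] <- cfg$bar_radii[by_len]
    # The printed centre distances put some centres closer than the sum of
    # the stated radii (physically impossible as separate solid bars), so
    # crowded bars are slimmed to clear their nearest neighbour by 3 mm;
    # bars must stay separate 26-connected components after voxelization.
    dmin <- as.matrix(stats::dist(X))
    diag(dmin) <- Inf
    for (i in 1:5) {
      allowed <- (min(dmin[i, ]) - 3) / 2
      radii[i] <- max(2, min(radii[i], floor(allowed * 2) / 2))
    }
    bars <- vector("list", 5)
    for (i in 1:5) {
      h <- lengths[i] / 2
      a <- X[i, ] - c(h, 0, 0)
      b <- X[i, ] + c(h, 0, 0)
      bars[[i]] <- bar_target(a, b, radii[i], paste0("Bar", i))
      # feasibility: sample the cylinder surface, demand strictly inside
      tt <- seq(-h, h, length.out = 21)
      probe <- cbind(X[i, 1] + tt, X[i, 2], X[i, 3])
      for (off in list(c(0, radii[i], 0), c(0, -radii[i], 0),
                       c(0, 0, radii[i]), c(0, 0, -radii[i]))) {
        pr <- sweep(probe, 2, off, `+`)
        if (!all(envelope_inside(env, pr, margin = 2)))
          stop("construction error: bar ", i, " overlaps the envelope")
      }
    }
    fids <- place_surface_fiducials(env, cfg$n_fiducials)
    entries <- t(vapply(bars, function(bb)
      surface_entry_at_depth(env, bb$centre,
                             envelope_top_z(env, bb$centre[1], bb$centre[2]) -
                               bb$centre[3]), numeric(3)))
    rownames(entries) <- paste0("Bar", 1:5)
    new_scene("anthropomorphic", env, fids, bars, needle_assembly(),
              default_patient_pose(), entries, seed,
              extra = list(embedding = emb))
  })
}

#' Build the porcine scene
#'
#' A pig-trunk superellipsoid with three implanted 2 x 1 mm point targets —
#' one kidney target at 107.6 mm depth and two liver targets at 123.7 and
#' 92.5 mm depth, each depth measured from its skin entry point to the
#' target centre — and twelve radiopaque squares on the skin.  Target
#' centres are snapped to the integer-mm lattice (see the methods vignette);
#' the entry point is then solved on the envelope surface so the stated
#' depths are exact.
#'
#' @inheritParams build_anthropomorphic_scene
#' @export
build_porcine_scene <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(envelope_mm = c(700, 350, 250),
                                n_fiducials = 12,
                                target_depths = c(kidney = 107.6,
                                                  liver1 = 123.7,
                                                  liver2 = 92.5),
                                target_xy = rbind(c(-120, -30), c(60, 10),
                                                  c(110, -20))),
                           config)
  env <- superellipsoid(cfg$envelope_mm / 2, exponent = 3)
  if (any(cfg$target_depths > cfg$envelope_mm[3]))
    stop("construction error: target depth exceeds the envelope thickness")
  with_local_seed(seed, {
    targets <- vector("list", length(cfg$target_depths))
    entries <- matrix(0, length(cfg$target_depths), 3,
                      dimnames = list(names(cfg$target_depths), NULL))
    for (i in seq_along(cfg$target_depths)) {
      ctr <- snap_target_centre(env, cfg$target_xy[i, ], cfg$target_depths[i])
      if (!envelope_inside(env, ctr, margin = 2))
        stop("construction error: target ", i, " outside the envelope")
      targets[[i]] <- point_target(ctr, label = names(cfg$target_depths)[i])
      entries[i, ] <- surface_entry_at_depth(env, ctr, cfg$target_depths[i])
    }
    fids <- place_surface_fiducials(env, cfg$n_fiducials)
    new_scene("porcine", env, fids, targets, needle_assembly(),
              default_patient_pose(), entries, seed)
  })
}

#' Build the cadaver scene
#'
#' A torso superellipsoid with two spherical liver lesions — 18 mm diameter
#' at 50.6 mm depth and 30 mm diameter at 91.2 mm depth (entry point to
#' lesion centre) — and twelve skin fiducials.
#'
#' @inheritParams build_anthropomorphic_scene
#' @export
build_cadaver_scene <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(envelope_mm = c(520, 360, 270),
                                n_fiducials = 12,
                                lesions = data.frame(
                                  label = c("met1", "met2"),
                                  diameter = c(18, 30),
                                  depth = c(50.6, 91.2),
                                  x = c(-50, 60), y = c(25, -15))),
                           config)
  env <- superellipsoid(cfg$envelope_mm / 2, exponent = 3)
  with_local_seed(seed, {
    n <- nrow(cfg$lesions)
    targets <- vector("list", n)
    entries <- matrix(0, n, 3, dimnames = list(cfg$lesions$label, NULL))
    for (i in seq_len(n)) {
      les <- cfg$lesions[i, ]
      ctr <- snap_target_centre(env, c(les$x, les$y), les$depth)
      if (!envelope_inside(env, ctr, margin = les$diameter / 2 + 2))
        stop("construction error: lesion ", i, " outside the envelope")
      targets[[i]] <- sphere_lesion(ctr, les$diameter, les$label)
      entries[i, ] <- surface_entry_at_depth(env, ctr, les$depth)
    }
    fids <- place_surface_fiducials(env, cfg$n_fiducials)
    new_scene("cadaver", env, fids, targets, needle_assembly(),
              default_patient_pose(), entries, seed)
  })
}

#' Serialise a scene to JSON and back
#'
#' The full ground truth — envelope, fiducials, targets, needle assembly,
#' patient pose, entry points — round-trips losslessly (numbers are written
#' at full precision).
#'
#' @param scene a `scene_spec`.
#' @param path JSON file path.
#' @return `write_scene()` returns `path` invisibly; `read_scene()` returns
#'   the `scene_spec`.
#' @export
write_scene <- function(scene, path) {
  ser_target <- function(tg) {
    base <- list(kind = class(tg)[1], label = tg$label, centre = tg$centre)
    if (inherits(tg, "bar_target"))
      c(base, list(endpoint_a = tg$endpoint_a, endpoint_b = tg$endpoint_b,
                   radius = tg$radius))
    else if (inherits(tg, "point_target")) c(base, list(extent = tg$extent))
    else c(base, list(diameter = tg$diameter))
  }
  obj <- list(
    scenario = scene$scenario,
    seed = scene$seed,
    envelope = list(semi_axes = scene$envelope$semi_axes,
                    exponent = scene$envelope$exponent,
                    centre = scene$envelope$centre),
    fiducials = lapply(scene$fiducials, function(f)
      list(label = f$label, centre = f$centre, normal = f$normal,
           axis1 = f$axis1, edge = f$edge, thickness = f$thickness)),
    targets = lapply(scene$targets, ser_target),
    needle = list(layout = apply(scene$needle$layout, 1, as.numeric,
                                 simplify = FALSE),
                  labels = rownames(scene$needle$layout),
                  tip_offset = scene$needle$tip_offset),
    patient_pose = as.numeric(t(as_homogeneous(scene$patient_pose))),
    entry_points = apply(scene$entry_points, 1, as.numeric, simplify = FALSE),
    entry_labels = rownames(scene$entry_points))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  env <- superellipsoid(num(j$envelope$semi_axes), j$envelope$exponent,
                        num(j$envelope$centre))
  fids <- lapply(j$fiducials, function(f)
    square_fiducial(num(f$centre), num(f$normal), num(f$axis1),
                    edge = f$edge, thickness = f$thickness, label = f$label))
  tgts <- lapply(j$targets, function(tg)
    switch(tg$kind,
           bar_target = bar_target(num(tg$endpoint_a), num(tg$endpoint_b),
                                   tg$radius, tg$label),
           point_target = point_target(num(tg$centre), num(tg$extent),
                                       tg$label),
           sphere_lesion = sphere_lesion(num(tg$centre), tg$diameter,
                                         tg$label)))
  layout <- do.call(rbind, lapply(j$needle$layout, num))
  rownames(layout) <- unlist(j$needle$labels)
  H <- matrix(num(j$patient_pose), 4, 4, byrow = TRUE)
  entries <- do.call(rbind, lapply(j$entry_points, num))
  rownames(entries) <- unlist(j$entry_labels)
  new_scene(j$scenario, env, fids, tgts,
            needle_assembly(layout, num(j$needle$tip_offset)),
            rigid_transform(project_so3(H[1:3, 1:3]), H[1:3, 4]),
            entries, j$seed)
}

#' Build a scene by scenario name
#' @param scenario one of `"anthro"`, `"porcine"`, `"cadaver"`.
#' @param config,seed passed to the scenario builder.
#' @return A `scene_spec`.
#' @export
build_scene <- function(scenario = c("anthro", "porcine", "cadaver"),
                        config = list(), seed = 1) {
  switch(match.arg(scenario),
         anthro = build_anthropomorphic_scene(config, seed),
         porcine = build_porcine_scene(config, seed),
         cadaver = build_cadaver_scene(config, seed))
}
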