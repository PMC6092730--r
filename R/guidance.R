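#' Needle tip position from the tracked handle pose
#'
#' The tip offset is a fixed handle-frame vector of norm 170 mm (17 cm
#' needle), calibrated once and applied to every pose.
#'
#' @param handle_pose `rigid_transform` (handle frame to world).
#' @param assembly a [needle_assembly()].
#' @return length-3 world tip position (mm).
#' @export
needle_tip <- function(handle_pose, assembly) {
  transform_points(handle_pose, assembly$tip_offset)
}

#' Tip-to-target distance
#'
#' The accuracy quantity: Euclidean distance between the needle tip and the
#' geometric centre of the target.  Zero means the needle is exactly at the
#' target centre.
#'
#' @param tip,centre length-3 positions (mm) in a common frame.
#' @return distance in mm.
#' @export
tip_to_target <- function(tip, centre) sqrt(sum((tip - centre)^2))

#' Augmented-reality overlay coordinates
#'
#' Maps CT-frame points through the estimated patient pose into the world
#' and projects them with the camera — the pixel coordinates at which
#' CT-derived structures are drawn over the live view.  No rasterisation is
#' performed.
#'
#' @param camera a [camera_model()].
#' @param patient_pose_estimate `rigid_transform`, CT frame to world.
#' @param ct_points N x 3 CT-frame points (mm); may be empty.
#' @return N x 2 pixel coordinates (0 x 2 for empty input).
#' @export
overlay_points <- function(camera, patient_pose_estimate, ct_points) {
  if (is.null(dim(ct_points))) ct_points <- matrix(ct_points, ncol = 3)
  if (nrow(ct_points) == 0) return(matrix(numeric(0), 0, 2))
  project(camera, transform_points(patient_pose_estimate, ct_points))
}

#' Default noise and controller configurations
#'
#' `default_noise_config()`: fiducial localisation sigma 0.5 mm (3-D noise on
#' tracked marker positions) and pixel sigma 0.5 px (camera detection
#' noise).  `default_controller_config()`: idealised operator advancing the
#' needle straight toward the displayed target in 5 mm steps, stopping when
#' the displayed distance falls to 0.5 mm (the physical protocol stops at a
#' displayed 0, unattainable with finite steps; 0.5 mm is below every
#' reported accuracy), with at most 500 steps.
#'
#' @return Named list of parameters.
#' @export
default_noise_config <- function() list(sigma_fid_mm = 0.5, sigma_px = 0.5)

#' @rdname default_noise_config
#' @export
default_controller_config <- function() {
  list(step_mm = 5, stop_tol_mm = 0.5, max_steps = 500)
}

#' Process a scene into the CT-side inputs of guidance
#'
#' Runs the pre-treatment stage once: voxelize, segment the fiducial and
#' target intensity bands, extract fiducial centroids (matched to scene
#' labels by nearest true centre — correspondence bookkeeping, not
#' measurement) and target centroids.
#'
#' @param scene a `scene_spec`.
#' @param spacing voxel spacing in mm (default 1).
#' @param keep_volume retain the intensity volume in the result?
#' @return A `processed_scene`: scene plus `ct_fiducials` (CT-frame
#'   [fiducial_set()] of segmented centroids), `ct_targets` (matrix of
#'   segmented target centroids, CT frame), `fiducial_count`,
#'   `target_count`.
#' @export
process_scene <- function(scene, spacing = 1, keep_volume = FALSE) {
  vol <- voxelize(scene, spacing = spacing)
  fb <- intensity_band("fiducial")
  tb <- intensity_band("target")
  lm_fid <- segment(vol, fb[1], fb[2], min_size = 4)
  lm_tgt <- segment(vol, tb[1], tb[2], min_size = 1)

  true_fid <- scene_fiducial_centres(scene)
  nf <- n_components(lm_fid)
  cent_f <- t(vapply(seq_len(nf), function(l) target_centre(lm_fid, l),
                     numeric(3)))
  # match segmented components to scene labels by nearest true centre
  match_f <- apply(cent_f, 1, function(p)
    which.min(colSums((t(true_fid$points) - p)^2)))
  if (anyDuplicated(match_f))
    warning("fiducial matching is not one-to-one (merged/split components?)")
  ct_fid <- fiducial_set(cent_f, true_fid$labels[match_f], frame = "CT")
  ord <- match(true_fid$labels, ct_fid$labels)
  ord <- ord[!is.na(ord)]
  ct_fid <- fiducial_set(ct_fid$points[ord, , drop = FALSE],
                         ct_fid$labels[ord], frame = "CT")

  true_tgt <- scene_target_centres(scene)
  nt <- n_components(lm_tgt)
  cent_t <- t(vapply(seq_len(nt), function(l) target_centre(lm_tgt, l),
                     numeric(3)))
  match_t <- apply(cent_t, 1, function(p)
    which.min(colSums((t(true_tgt) - p)^2)))
  ct_tgt <- matrix(NA_real_, nrow(true_tgt), 3,
                   dimnames = list(rownames(true_tgt), NULL))
  ct_tgt[match_t, ] <- cent_t

  out <- c(scene, list(ct_fiducials = ct_fid, ct_targets = ct_tgt,
                       fiducial_count = nf, target_count = nt,
                       spacing = spacing))
  if (keep_volume) out$volume <- vol
  class(out) <- c("processed_scene", "scene_spec")
  out
}

#' Simulate one augmented-reality guided needle insertion
#'
#' The tracking loop of the guidance system, per step: (1) sample a
#' respiratory phase (gated = reference phase, free = uniform); (2) simulate
#' camera observations of the patient skin markers and the handle markers at
#' their true, motion-displaced world positions; (3) estimate both poses;
#' (4) register the CT fiducial centroids to the tracked patient-marker
#' positions (fiducial localisation noise enters here); (5) compute the
#' displayed tip position in the CT frame and the displayed tip-to-target
#' distance; (6) advance the true handle by `min(step_mm, displayed)` along
#' the displayed tip-to-target direction.  The loop stops when the displayed
#' distance is at most `stop_tol_mm` or after `max_steps`.  Registration is
#' refreshed every step (continuous tracking); internal targets are never
#' re-imaged intra-procedure.
#'
#' @param pscene a [process_scene()] result.
#' @param target label or index of the target to reach.
#' @param camera a [camera_model()]; default an overhead camera 400 mm above
#'   the skin entry point.
#' @param noise list, see [default_noise_config()].
#' @param respiration a [respiratory_model()] or `NULL` for a rigid scene.
#' @param mode `"GATED"` or `"FREE"`.
#' @param controller list, see [default_controller_config()].
#' @param seed integer seed for this insertion (isolated RNG stream).
#' @return An `insertion_result`: list with `trajectory` (data.frame of per
#'   step readouts), `final_true_error_mm`, `steps`, `hit` (displayed
#'   distance reached `stop_tol_mm`), `aborted`.
#' @export
simulate_insertion <- function(pscene, target = 1, camera = NULL,
                               noise = default_noise_config(),
                               respiration = NULL,
                               mode = c("GATED", "FREE"),
                               controller = default_controller_config(),
                               seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(pscene, "processed_scene"))
  if (is.character(target)) target <- match(target, rownames(pscene$ct_targets))
  if (is.na(target) || target < 1 || target > nrow(pscene$ct_targets))
    stop("no such target in the scene")
  if (is.null(respiration)) respiration <- respiratory_model(amplitude = c(0, 0, 0))

  Tp <- pscene$patient_pose                  # CT -> world (true)
  ct_fid <- pscene$ct_fiducials              # CT centroids (layout & reg source)
  true_fid <- scene_fiducial_centres(pscene)
  true_fid_pts <- true_fid$points[ct_fid$labels, , drop = FALSE]
  tgt_ct <- pscene$ct_targets[target, ]      # displayed target (CT frame)
  tgt_true_ct <- scene_target_centres(pscene)[target, ]
  entry <- pscene$entry_points[target, ]
  entry_w <- transform_points(Tp, entry)

  if (is.null(camera))
    camera <- overhead_camera(distance = 400, look_at = entry_w)

  assembly <- pscene$needle
  # initial true handle pose: tip at the entry point, needle axis vertical
  handle_pose <- rigid_transform(diag(3), entry_w - assembly$tip_offset)

  # Respiratory phases come from their own substream so that gated and free
  # runs with identical seeds see identical noise realisations (a
  # zero-amplitude free run is then bit-identical to the gated run).
  phases <- if (mode == "GATED") {
    rep(respiration$reference_phase, controller$max_steps)
  } else {
    with_local_seed(as.integer((as.double(seed) + 499999) %%
                                 .Machine$integer.max),
                    replicate(controller$max_steps,
                              sample_phase("FREE", respiration)))
  }

  with_local_seed(seed, {
    traj <- vector("list", controller$max_steps)
    skips <- 0
    aborted <- FALSE
    hit <- FALSE
    est_patient_prev <- NULL
    est_handle_prev <- NULL
    phase <- respiration$reference_phase
    step_count <- 0

    for (step in seq_len(controller$max_steps)) {
      phase <- phases[step]
      d_skin <- respiratory_displacement(respiration, "skin", phase)
      d_tgt <- respiratory_displacement(respiration, "target", phase)

      # true, motion-displaced marker positions in the world
      fid_world <- sweep(transform_points(Tp, true_fid_pts), 2, d_skin, `+`)

      obs_p <- observe_world(camera, fid_world, ct_fid$labels, noise$sigma_px)
      obs_h <- observe(camera, assembly$layout, handle_pose, noise$sigma_px)
      est_p <- try_pose(obs_p, ct_fid$points, camera, est_patient_prev)
      est_h <- try_pose(obs_h, assembly$layout, camera, est_handle_prev)
      if (is.null(est_p) || is.null(est_h) ||
          !est_p$converged || !est_h$converged) {
        skips <- skips + 1
        if (skips > 20) { aborted <- TRUE; break }
        next
      }
      skips <- 0
      est_patient_prev <- est_p$pose
      est_handle_prev <- est_h$pose

      # tracked patient-marker world positions (localisation noise enters)
      tracked <- transform_points(est_p$pose, ct_fid$points)
      if (noise$sigma_fid_mm > 0)
        tracked <- tracked + matrix(stats::rnorm(length(tracked), 0,
                                                 noise$sigma_fid_mm),
                                    ncol = 3)
      reg <- register_rigid(ct_fid,
                            fiducial_set(tracked, ct_fid$labels,
                                         frame = "TRACKER"))

      tip_true <- needle_tip(handle_pose, assembly)
      tip_disp_ct <- transform_points(invert_transform(reg$transform),
                                      needle_tip(est_h$pose, assembly))
      disp_dist <- tip_to_target(tip_disp_ct, tgt_ct)
      true_target_w <- transform_points(Tp, tgt_true_ct) + d_tgt
      true_dist <- tip_to_target(tip_true, true_target_w)

      step_count <- step_count + 1
      traj[[step_count]] <- data.frame(
        step = step_count, phase = phase,
        disp_x = tip_disp_ct[1], disp_y = tip_disp_ct[2],
        disp_z = tip_disp_ct[3],
        displayed_mm = disp_dist, true_error_mm = true_dist)

      if (disp_dist <= controller$stop_tol_mm) { hit <- TRUE; break }

      # idealised operator: straight step toward the displayed target
      dir_ct <- (tgt_ct - tip_disp_ct) / disp_dist
      dir_w <- as.numeric(reg$transform$R %*% dir_ct)
      advance <- min(controller$step_mm, disp_dist)
      handle_pose <- rigid_transform(handle_pose$R,
                                     handle_pose$t + advance * dir_w)
    }
    trajectory <- do.call(rbind, traj[seq_len(step_count)])
    if (is.null(trajectory) || nrow(trajectory) == 0)
      stop("insertion aborted before any pose could be estimated")
    structure(list(trajectory = trajectory,
                   final_true_error_mm = trajectory$true_error_mm[step_count],
                   final_displayed_mm = trajectory$displayed_mm[step_count],
                   steps = step_count, hit = hit, aborted = aborted,
                   target = rownames(pscene$ct_targets)[target]),
              class = "insertion_result")
  })
}

# observe pre-posed world points (identity object pose)
observe_world <- function(camera, pts_world, labels, sigma_px) {
  rownames(pts_world) <- labels
  observe(camera, pts_world, rigid_identity(), sigma_px)
}

try_pose <- function(obs, layout, camera, init) {
  tryCatch(estimate_pose(obs, layout, camera, init = init),
           error = function(e) NULL)
}

#' @export
print.insertion_result <- function(x, ...) {
  cat("<insertion_result> target:", x$target, "| steps:", x$steps,
      "| hit:", x$hit,
      "| final displayed:", round(x$final_displayed_mm, 3), "mm",
      "| final true error:", round(x$final_true_error_mm, 3), "mm\n")
  invisible(x)
}

#' Write an insertion result to JSON (and optionally the trajectory to CSV)
#' @param result an `insertion_result`.
#' @param path JSON output path.
#' @param trajectory_csv optional CSV path for the per-step readouts.
#' @return `path`, invisibly.
#' @export
write_insertion <- function(result, path, trajectory_csv = NULL) {
  jsonlite::write_json(
    list(target = result$target, steps = result$steps, hit = result$hit,
         aborted = result$aborted,
         final_displayed_mm = result$final_displayed_mm,
         final_true_error_mm = result$final_true_error_mm),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(trajectory_csv))
    utils::write.csv(result$trajectory, trajectory_csv, row.names = FALSE)
  invisible(path)
}
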