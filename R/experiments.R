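#' Accuracy report
#'
#' Per-trial targeting errors with mean, SD and the pass flag against the
#' clinical accuracy threshold (default 5 mm: thermal ablation of 1-3 cm
#' tumours requires the tip within 5 mm of the target centre for single
#' session complete necrosis).  SD uses the population convention (divide by
#' n), recorded in the report; for a single trial the SD is 0.
#'
#' @param errors numeric vector of per-trial errors (mm).
#' @param threshold accuracy threshold (mm), default 5.
#' @return An `accuracy_report`: list with `errors`, `mean`, `sd`,
#'   `threshold`, `pass` (`mean < threshold`), `sd_convention`.
#' @export
accuracy_report <- function(errors, threshold = 5) {
  errors <- as.numeric(errors)
  if (!length(errors)) stop("empty error vector")
  m <- mean(errors)
  s <- sqrt(mean((errors - m)^2))   # population SD
  structure(list(errors = errors, mean = m, sd = s, threshold = threshold,
                 pass = m < threshold, sd_convention = "population"),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "<accuracy_report> n = %d | mean = %.2f mm | SD = %.2f mm | %s %g mm threshold\n",
    length(x$errors), x$mean, x$sd,
    if (x$pass) "PASS (mean below)" else "FAIL (mean at/above)", x$threshold))
  invisible(x)
}

#' Pairwise distance table
#'
#' One row per unordered target pair: the ground-truth ("real") distance
#' between target centres and the pipeline-measured ("virtual") distance,
#' with their absolute difference.  Virtual distances are 3-D distances
#' between pipeline-mapped centres, not 2-D on-screen distances — the
#' millimetre accuracy framing of the study implies the 3-D reading.
#'
#' @param labels character vector of target labels.
#' @param real,virtual matrices or named vectors of centre positions /
#'   distances, see [run_anthropomorphic()].
#' @return data.frame of class `pairwise_distance_table` with columns
#'   `pair`, `real_mm`, `virtual_mm`, `abs_diff_mm`.
#' @export
pairwise_distance_table <- function(labels, real, virtual) {
  n <- length(labels)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    rows[[length(rows) + 1]] <- data.frame(
      pair = paste0(labels[i], "-", labels[j]),
      real_mm = real[i, j], virtual_mm = virtual[i, j],
      abs_diff_mm = abs(real[i, j] - virtual[i, j]))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pairwise_distance_table", class(out))
  out
}

#' Mean and SD of a distance table's absolute-difference column
#'
#' @param table a [pairwise_distance_table()] or any data.frame with an
#'   `abs_diff_mm` column (e.g. [reference_bar_distances()]).
#' @return list with `mean_mm` and `sd_mm` (population SD).
#' @export
distance_table_stats <- function(table) {
  if (!nrow(table)) stop("empty distance table")
  x <- table$abs_diff_mm
  m <- mean(x)
  list(mean_mm = m, sd_mm = sqrt(mean((x - m)^2)))
}

# virtual target centres for one trial: the full measurement pipeline
# (CT centroids -> camera observation of skin markers -> pose -> fiducial
# localisation noise -> registration), then CT target centroids mapped to
# the world through the estimated registration.
virtual_target_centres <- function(pscene, camera, noise) {
  ct_fid <- pscene$ct_fiducials
  true_fid <- scene_fiducial_centres(pscene)
  fid_world <- transform_points(pscene$patient_pose,
                                true_fid$points[ct_fid$labels, , drop = FALSE])
  obs <- observe_world(camera, fid_world, ct_fid$labels, noise$sigma_px)
  est <- estimate_pose(obs, ct_fid$points, camera)
  tracked <- transform_points(est$pose, ct_fid$points)
  if (noise$sigma_fid_mm > 0)
    tracked <- tracked + matrix(stats::rnorm(length(tracked), 0,
                                             noise$sigma_fid_mm), ncol = 3)
  reg <- register_rigid(ct_fid, fiducial_set(tracked, ct_fid$labels,
                                             frame = "TRACKER"))
  transform_points(reg$transform, pscene$ct_targets)
}

#' Anthropomorphic trunk-phantom accuracy study
#'
#' For every unordered pair of the five bars, compares the ground-truth
#' centre-to-centre distance against the distance between the same centres
#' measured through the full pipeline (voxelize, segment, PCA centroids,
#' camera observation, pose, registration), averaged over `n_trials` trials
#' at each camera-to-phantom distance in `camera_distances`.
#'
#' @param config scene config, see [build_anthropomorphic_scene()].
#' @param n_trials trials per camera distance (>= 1).
#' @param seed integer seed.
#' @param noise see [default_noise_config()]; set both sigmas to 0 for the
#'   noiseless pipeline.
#' @param camera_distances mm; default `c(300, 400, 500)`.
#' @param spacing voxel spacing (mm).
#' @param pscene optional pre-processed scene (skips voxelization).
#' @return list with `table` (a [pairwise_distance_table()]), `report`
#'   (an [accuracy_report()] over the absolute differences), `stats`.
#' @export
run_anthropomorphic <- function(config = list(), n_trials = 10, seed = 1,
                                noise = default_noise_config(),
                                camera_distances = c(300, 400, 500),
                                spacing = 1, pscene = NULL) {
  stopifnot(n_trials >= 1)
  if (is.null(pscene))
    pscene <- process_scene(build_anthropomorphic_scene(config, seed),
                            spacing = spacing)
  labels <- rownames(pscene$ct_targets)
  true_d <- as.matrix(stats::dist(scene_target_centres(pscene)))
  acc <- matrix(0, length(labels), length(labels))
  n_ok <- 0
  with_local_seed(seed + 1L, {
    for (cd in camera_distances) {
      camera <- overhead_camera(distance = cd,
                                look_at = transform_points(
                                  pscene$patient_pose, colMeans(pscene$ct_targets)))
      for (tr in seq_len(n_trials)) {
        vc <- tryCatch(virtual_target_centres(pscene, camera, noise),
                       error = function(e) {
                         message("trial dropped: ", conditionMessage(e)); NULL
                       })
        if (is.null(vc)) next
        acc <- acc + as.matrix(stats::dist(vc))
        n_ok <- n_ok + 1
      }
    }
  })
  if (n_ok == 0) stop("all trials failed")
  virt_d <- acc / n_ok
  tab <- pairwise_distance_table(labels, true_d, virt_d)
  list(table = tab, report = accuracy_report(tab$abs_diff_mm),
       stats = distance_table_stats(tab), n_trials_used = n_ok)
}

#' Porcine respiratory accuracy study
#'
#' Simulated insertions into the kidney and both liver targets under gated
#' (breath-hold at the planning-CT phase) or free breathing, aggregating the
#' final true tip-to-target-centre errors.
#'
#' @param config scene config, see [build_porcine_scene()].
#' @param gated logical: breath-hold (`TRUE`) or free breathing.
#' @param n_reps insertions per target.
#' @param seed integer seed; rep `r` of target `k` uses an isolated seed
#'   derived from it.
#' @param noise,respiration,controller see [simulate_insertion()].
#' @param spacing voxel spacing (mm).
#' @param pscene optional pre-processed scene.
#' @return An [accuracy_report()] with attribute `per_target` (named list of
#'   per-target reports).
#' @export
run_porcine <- function(config = list(), gated = TRUE, n_reps = 100, seed = 1,
                        noise = default_noise_config(),
                        respiration = respiratory_model(),
                        controller = default_controller_config(),
                        spacing = 1, pscene = NULL) {
  if (is.null(pscene))
    pscene <- process_scene(build_porcine_scene(config, seed),
                            spacing = spacing)
  run_insertion_series(pscene, gated, n_reps, seed, noise, respiration,
                       controller)
}

# derive an isolated, overflow-safe 32-bit seed for one run
derive_seed <- function(seed, k, r) {
  as.integer((as.double(seed) * 100000 + k * 1000 + r) %%
               (.Machine$integer.max - 1e6))
}

run_insertion_series <- function(pscene, gated, n_reps, seed, noise,
                                 respiration, controller) {
  mode <- if (gated) "GATED" else "FREE"
  targets <- rownames(pscene$ct_targets)
  per_target <- list()
  errors <- c()
  for (k in seq_along(targets)) {
    errs <- vapply(seq_len(n_reps), function(r) {
      res <- simulate_insertion(pscene, target = k, noise = noise,
                                respiration = respiration, mode = mode,
                                controller = controller,
                                seed = derive_seed(seed, k, r))
      res$final_true_error_mm
    }, numeric(1))
    per_target[[targets[k]]] <- accuracy_report(errs)
    errors <- c(errors, errs)
  }
  rep_all <- accuracy_report(errors)
  attr(rep_all, "per_target") <- per_target
  rep_all
}

#' Cadaver liver-lesion accuracy study
#'
#' Gated insertions into both liver lesions (18 mm at 50.6 mm depth, 30 mm
#' at 91.2 mm depth).  The per-lesion reports carry the lesion diameter and
#' the hit rate, where a hit means the final true tip lies inside the lesion
#' sphere.
#'
#' @inheritParams run_porcine
#' @return An [accuracy_report()] with attribute `per_target`; each
#'   per-lesion report has `diameter_mm` and `hit_rate` attributes.
#' @export
run_cadaver <- function(config = list(), n_reps = 100, seed = 1,
                        noise = default_noise_config(),
                        controller = default_controller_config(),
                        spacing = 1, pscene = NULL) {
  if (is.null(pscene))
    pscene <- process_scene(build_cadaver_scene(config, seed),
                            spacing = spacing)
  targets <- rownames(pscene$ct_targets)
  diam <- vapply(pscene$targets, `[[`, numeric(1), "diameter")
  per_target <- list()
  errors <- c()
  for (k in seq_along(targets)) {
    errs <- vapply(seq_len(n_reps), function(r) {
      res <- simulate_insertion(pscene, target = k, noise = noise,
                                respiration = NULL, mode = "GATED",
                                controller = controller,
                                seed = derive_seed(seed, k, r))
      res$final_true_error_mm
    }, numeric(1))
    rep_k <- accuracy_report(errs)
    attr(rep_k, "diameter_mm") <- diam[k]
    attr(rep_k, "hit_rate") <- mean(errs <= diam[k] / 2)
    per_target[[targets[k]]] <- rep_k
    errors <- c(errors, errs)
  }
  rep_all <- accuracy_report(errors)
  attr(rep_all, "per_target") <- per_target
  rep_all
}

#' Write an accuracy report (plus any per-target reports) to JSON
#' @param report an [accuracy_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_accuracy_report <- function(report, path) {
  as_list <- function(r) {
    out <- list(n = length(r$errors), mean_mm = r$mean, sd_mm = r$sd,
                sd_convention = r$sd_convention, threshold_mm = r$threshold,
                pass = r$pass, errors_mm = r$errors)
    if (!is.null(attr(r, "diameter_mm"))) {
      out$diameter_mm <- attr(r, "diameter_mm")
      out$hit_rate <- attr(r, "hit_rate")
    }
    out
  }
  top <- as_list(report)
  pt <- attr(report, "per_target")
  if (!is.null(pt)) top$per_target <- lapply(pt, as_list)
  jsonlite::write_json(top, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
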