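# Shared fixtures.  Scene processing (voxelize + segment at 1 mm) takes tens
# of seconds per scenario, so processed scenes are built lazily and cached
# for the whole test run.
.fixture_env <- new.env(parent = emptyenv())

cached_scene <- function(scenario, seed = 1) {
  key <- paste0("scene_", scenario, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_scene(scenario, seed = seed)
  .fixture_env[[key]]
}

cached_pscene <- function(scenario, seed = 1) {
  key <- paste0("pscene_", scenario, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- process_scene(cached_scene(scenario, seed),
                                         spacing = 1)
  .fixture_env[[key]]
}

zero_noise <- function() list(sigma_fid_mm = 0, sigma_px = 0)

# a compact non-coplanar labelled point set for registration tests
quad_points <- function() {
  rbind(c(0, 0, 0), c(100, 0, 0), c(0, 80, 0), c(20, 30, 60))
}

# small scene with a handful of fiducials/targets for fast voxel tests
mini_scene <- function(with_fiducial = TRUE, with_target = TRUE,
                       tilt_deg = 0) {
  env <- endoguide:::superellipsoid(c(60, 50, 40), exponent = 3)
  fids <- list()
  if (with_fiducial) {
    nrm <- c(sin(tilt_deg * pi / 180), 0, cos(tilt_deg * pi / 180))
    ax1 <- c(cos(tilt_deg * pi / 180), 0, -sin(tilt_deg * pi / 180))
    fids <- list(square_fiducial(c(10, 20, 30), nrm, ax1, label = "F1"))
  }
  tgts <- if (with_target) list(sphere_lesion(c(0, 0, 0), 20, "S1")) else list()
  endoguide:::new_scene("mini", env, fids, tgts, needle_assembly(),
                        rigid_identity(),
                        matrix(c(0, 0, 40), 1, 3,
                               dimnames = list("S1", NULL)), 0L)
}
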