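#' Parametric respiratory motion model
#'
#' Raised-cosine periodic displacement with zero displacement at the
#' reference phase (phase 0 = maximum expiration, the phase at which the
#' planning CT is acquired): `d(t) = A * (1 - cos(2 pi t)) / 2`.
#'
#' Internal targets move along the cranio-caudal amplitude vector; skin
#' fiducials move by `skin_coupling * |A|` along `skin_direction`.  The
#' default skin direction is the anteroposterior axis (the abdominal wall
#' rises while internal organs slide cranio-caudally); set
#' `skin_direction = amplitude / |amplitude|` to force skin motion parallel
#' to target motion instead — in that case a rigid registration to the skin
#' markers absorbs the common translation and partially compensates the
#' target motion (see the methods vignette for why the anteroposterior
#' default is the physically faithful choice).
#'
#' @param period breathing period in seconds (> 0); only used when
#'   converting wall-clock times to phases.
#' @param amplitude length-3 peak internal displacement vector (mm); default
#'   12 mm cranio-caudal (along the body long axis, world x), a
#'   literature-typical abdominal value.
#' @param skin_coupling dimensionless factor in `[0, 1]` (default 0.3).
#' @param skin_direction unit vector of skin marker motion (default
#'   anteroposterior, world +z).
#' @param reference_phase phase of the planning CT (default 0).
#' @return A `respiratory_model`.
#' @export
respiratory_model <- function(period = 4, amplitude = c(12, 0, 0),
                              skin_coupling = 0.3,
                              skin_direction = c(0, 0, 1),
                              reference_phase = 0) {
  stopifnot(period > 0, length(amplitude) == 3L,
            skin_coupling >= 0, skin_coupling <= 1)
  nsd <- sqrt(sum(skin_direction^2))
  if (nsd == 0) stop("skin_direction must be non-zero")
  structure(list(period = period, amplitude = as.numeric(amplitude),
                 skin_coupling = skin_coupling,
                 skin_direction = as.numeric(skin_direction) / nsd,
                 reference_phase = reference_phase),
            class = "respiratory_model")
}

#' Displacement of a structure at a respiratory phase
#'
#' @param model a [respiratory_model()].
#' @param structure `"target"` or `"skin"`.
#' @param phase phase in `[0, 1)`.
#' @return length-3 displacement (mm); zero at phase 0 for every structure.
#' @export
respiratory_displacement <- function(model, structure = c("target", "skin"),
                                     phase) {
  structure <- match.arg(structure)
  stopifnot(phase >= 0, phase < 1)
  s <- (1 - cos(2 * pi * (phase - model$reference_phase))) / 2
  if (structure == "target") {
    model$amplitude * s
  } else {
    model$skin_coupling * sqrt(sum(model$amplitude^2)) * model$skin_direction * s
  }
}

#' Sample a respiratory phase
#'
#' `GATED` returns the reference phase exactly (needle work restricted to
#' the planning-CT phase, i.e. breath-hold); `FREE` draws a uniform random
#' phase from the current RNG stream.
#'
#' @param mode `"GATED"` or `"FREE"`.
#' @param model a [respiratory_model()] (supplies the reference phase).
#' @return A phase in `[0, 1)`.
#' @export
sample_phase <- function(mode = c("GATED", "FREE"),
                         model = respiratory_model()) {
  mode <- match.arg(mode)
  if (mode == "GATED") model$reference_phase else stats::runif(1)
}
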