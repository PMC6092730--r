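#' Labelled fiducial point sets
#'
#' A `fiducial_set` holds labelled 3-D marker positions together with the
#' coordinate frame they live in: `"CT"` for positions derived from the
#' planning scan, `"TRACKER"` for positions delivered by the camera tracking
#' stage.  Registration consumes one set in each frame.
#'
#' @param points N x 3 numeric matrix of positions (mm).
#' @param labels character vector of unique marker identifiers; defaults to
#'   `"F1" ... "FN"`.
#' @param frame `"CT"` or `"TRACKER"`.
#' @return A `fiducial_set`.
#' @export
fiducial_set <- function(points, labels = NULL, frame = c("CT", "TRACKER")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 3L)
    stop("points must be an N x 3 matrix")
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (is.null(labels)) labels <- paste0("F", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("need one label per point")
  if (anyDuplicated(labels)) stop("fiducial labels must be unique")
  if (!all(is.finite(points))) stop("fiducial coordinates must be finite")
  rownames(points) <- labels
  structure(list(points = points, labels = labels, frame = frame),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("<fiducial_set> ", nrow(x$points), " points in frame ", x$frame, "\n",
      sep = "")
  print(utils::head(round(x$points, 3)))
  if (nrow(x$points) > 6) cat("...\n")
  invisible(x)
}

#' Test a point configuration for (near-)collinearity
#'
#' A configuration is degenerate for rigid registration when its centred
#' point matrix has numerical rank < 2, i.e. all points lie on a line.  The
#' test compares the second singular value against `tol` times the largest.
#' Planar sets are *not* degenerate: a plane still pins down the full
#' rotation once reflections are excluded.
#'
#' @param points N x 3 matrix (mm).
#' @param tol relative singular-value threshold (default `1e-6`, which
#'   separates machine noise from genuinely flat configurations at mm scale).
#' @return `TRUE` if the configuration is collinear/degenerate.
#' @export
is_collinear <- function(points, tol = 1e-6) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) return(TRUE)
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  sv[2] <= tol * sv[1]
}

check_registrable <- function(fs) {
  if (nrow(fs$points) < 3L)
    stop("registration requires at least 3 fiducials, got ", nrow(fs$points))
  if (is_collinear(fs$points))
    stop("degenerate fiducial configuration: points are collinear")
  invisible(TRUE)
}

#' Read / write fiducial sets as CSV
#'
#' The dialect is `label,x_mm,y_mm,z_mm,frame` with a header row.  A file may
#' only contain one frame.
#'
#' @param path file path.
#' @return `read_fiducials()` returns a `fiducial_set`;
#'   `write_fiducials()` returns `path` invisibly.
#' @export
read_fiducials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm", "frame")
  if (!all(need %in% names(d)))
    stop("fiducial CSV must have columns: ", paste(need, collapse = ", "))
  frames <- unique(d$frame)
  if (length(frames) != 1L)
    stop("fiducial CSV mixes frames: ", paste(frames, collapse = ", "))
  fiducial_set(cbind(d$x_mm, d$y_mm, d$z_mm), d$label, frame = frames)
}

#' @rdname read_fiducials
#' @param fs a `fiducial_set`.
#' @export
write_fiducials <- function(fs, path) {
  stopifnot(inherits(fs, "fiducial_set"))
  d <- data.frame(label = fs$labels,
                  x_mm = fs$points[, 1],
                  y_mm = fs$points[, 2],
                  z_mm = fs$points[, 3],
                  frame = fs$frame)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
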