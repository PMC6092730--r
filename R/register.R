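#' Closed-form rigid point-set registration
#'
#' Least-squares rigid alignment of two labelled fiducial sets with known
#' correspondence (Kabsch/Horn family): the returned transform minimises
#' `sum_i || T(src_i) - dst_i ||^2` over proper rigid motions.  The rotation
#' comes from the SVD of the cross-covariance of the centred point sets with
#' a determinant sign correction, so a reflection is never returned even
#' when the unconstrained optimum would be one (e.g. mirrored coplanar
#' configurations).
#'
#' The fiducial registration error (FRE) is reported as the *root mean
#' square* residual over fiducials — stated explicitly because mean-residual
#' conventions also exist in the literature.
#'
#' @param src,dst `fiducial_set` objects with identical labels in identical
#'   order; `src` is mapped onto `dst`.
#' @return A `registration_result`: list with `transform`
#'   (`rigid_transform`), `fre` (mm, RMS), and `per_fiducial_residuals`
#'   (named numeric, mm).
#' @examples
#' pts <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 80, 0), c(0, 0, 60))
#' src <- fiducial_set(pts, frame = "CT")
#' tf <- rigid_transform(rot_axis_angle(c(1, 1, 1), 0.5), c(5, -3, 2))
#' dst <- fiducial_set(transform_points(tf, pts), frame = "TRACKER")
#' register_rigid(src, dst)$fre
#' @export
register_rigid <- function(src, dst) {
  stopifnot(inherits(src, "fiducial_set"), inherits(dst, "fiducial_set"))
  if (!identical(src$labels, dst$labels))
    stop("correspondence error: src and dst labels differ or are reordered")
  check_registrable(src)
  check_registrable(dst)

  P <- src$points
  Q <- dst$points
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)            # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- as.numeric(cq - R %*% cp)
  tf <- rigid_transform(project_so3(R), tvec)

  mapped <- transform_points(tf, P)
  res <- sqrt(rowSums((mapped - Q)^2))
  names(res) <- src$labels
  structure(list(transform = tf,
                 fre = sqrt(mean(res^2)),
                 per_fiducial_residuals = res),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> FRE (RMS) =", format(round(x$fre, 4)), "mm over",
      length(x$per_fiducial_residuals), "fiducials\n")
  print(x$transform)
  invisible(x)
}

#' Target registration error
#'
#' Distance between a probe point mapped by the estimated registration and
#' by the true map — the clinically relevant error at a non-fiducial
#' location (e.g. a tumour centre).
#'
#' @param reg a `registration_result` (or a bare `rigid_transform`).
#' @param true_map the ground-truth `rigid_transform`.
#' @param probe length-3 probe point (mm) in the source frame.
#' @return TRE in mm (non-negative scalar).
#' @export
target_registration_error <- function(reg, true_map, probe) {
  tf <- if (inherits(reg, "registration_result")) reg$transform else reg
  stopifnot(inherits(tf, "rigid_transform"), inherits(true_map, "rigid_transform"))
  sqrt(sum((transform_points(tf, probe) - transform_points(true_map, probe))^2))
}

#' Exhaustive correspondence search for small marker sets
#'
#' The physical system identifies markers by recognising their geometric
#' configuration; this helper reproduces that for unlabelled sets by trying
#' every permutation of `dst` against `src` (feasible for N <= 8) and
#' keeping the one with minimal FRE.  Ties are broken by the
#' lexicographically smallest permutation.
#'
#' @param src,dst `fiducial_set` objects of equal size (N <= 8); labels of
#'   `dst` are treated as unknown.
#' @return List with `permutation` (indices into `dst` matching `src` order),
#'   and `result` (the winning `registration_result`).
#' @export
match_fiducials <- function(src, dst) {
  n <- nrow(src$points)
  if (n != nrow(dst$points)) stop("sets must have equal size")
  if (n > 8) stop("exhaustive matching supported for N <= 8 only")
  perms <- permutations_lex(n)
  best <- NULL
  best_perm <- NULL
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    dperm <- fiducial_set(dst$points[p, , drop = FALSE], src$labels,
                          frame = dst$frame)
    r <- register_rigid(src, dperm)
    if (is.null(best) || r$fre < best$fre - 1e-12) {  # strict improvement
      best <- r
      best_perm <- p
    }
  }
  list(permutation = best_perm, result = best)
}

# All permutations of 1..n in lexicographic row order.
permutations_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_lex(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Write a registration result to JSON
#'
#' Serialises the 4x4 homogeneous matrix (row-major), the FRE and the
#' per-fiducial residuals.
#'
#' @param reg a `registration_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registration <- function(reg, path) {
  stopifnot(inherits(reg, "registration_result"))
  H <- as_homogeneous(reg$transform)
  jsonlite::write_json(
    list(matrix_4x4_row_major = as.numeric(t(H)),
         fre_mm = reg$fre,
         per_fiducial_residuals_mm = as.list(reg$per_fiducial_residuals)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a registration result written by [write_registration()]
#' @param path JSON path.
#' @return A `registration_result`.
#' @export
read_registration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- matrix(as.numeric(j$matrix_4x4_row_major), 4, 4, byrow = TRUE)
  res <- unlist(j$per_fiducial_residuals_mm)
  structure(list(transform = rigid_transform(project_so3(H[1:3, 1:3]), H[1:3, 4]),
                 fre = as.numeric(j$fre_mm),
                 per_fiducial_residuals = res),
            class = "registration_result")
}
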