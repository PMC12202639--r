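# Sagittal spinal angles (Cobb construction) from vertebral endplate
# corner landmarks: cervical lordosis (CC), thoracic kyphosis (TTK) and
# lumbar lordosis (LL).
#
# All three are computed as signed angles between two endplate lines in
# an intrinsic sagittal frame derived from the landmarks themselves
# (cranio-caudal axis from the vertebra centroids, anterior axis from
# the posterior->anterior corner directions), which makes the angles
# exactly invariant under rigid motion and uniform scaling of the
# landmark set.

#' Orthogonally project 3D points onto a plane
#'
#' Projects onto the plane through the origin with the given normal
#' (the component along the normal is removed). Projection is
#' idempotent.
#'
#' @param points n x 3 numeric matrix.
#' @param normal Length-3 non-zero normal vector.
#' @return n x 3 matrix of projected points.
#' @export
project_to_plane <- function(points, normal) {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn == 0) stop("project_to_plane: zero plane normal")
  normal <- normal / nn
  points <- as.matrix(points)
  points - outer(drop(points %*% normal), normal)
}

# least-squares plane normal of a point set: smallest right singular
# vector of the centered coordinates
.ls_plane_normal <- function(points) {
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2L, ctr))
  sv$v[, 3L]
}

.spine_points <- function(spine) {
  do.call(rbind, lapply(spine$vertebrae, function(v)
    rbind(v$sup_ant, v$sup_post, v$inf_ant, v$inf_post)))
}

#' Project spine landmarks into an intrinsic sagittal 2D frame
#'
#' Projects all endplate corners onto the sagittal plane and expresses
#' them in a 2D frame computed from the anatomy itself: the in-plane
#' y-axis points cranially (from the most caudal to the most cranial
#' vertebra centroid) and the in-plane x-axis points anteriorly (mean
#' posterior-to-anterior corner direction, orthogonalized against the
#' y-axis). By default the sagittal plane is the least-squares plane of
#' all corner landmarks; a plane normal can be supplied instead.
#'
#' @param spine A [spine_landmarks()].
#' @param plane_normal Optional length-3 normal of the sagittal plane;
#'   default: least-squares fit.
#' @return A list of class `spine_landmarks_2d` mirroring the input but
#'   with length-2 (anterior, cranial) coordinates per corner.
#' @export
sagittal_project <- function(spine, plane_normal = NULL) {
  stopifnot(inherits(spine, "spine_landmarks"))
  pts <- .spine_points(spine)
  normal <- if (is.null(plane_normal)) .ls_plane_normal(pts)
            else as.numeric(plane_normal)
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn == 0) stop("sagittal_project: zero plane normal")
  normal <- normal / nn
  proj <- function(p) p - sum(p * normal) * normal

  centroids <- t(vapply(spine$vertebrae, function(v)
    proj((v$sup_ant + v$sup_post + v$inf_ant + v$inf_post) / 4), numeric(3)))
  n_v <- nrow(centroids)
  e_up <- centroids[1L, ] - centroids[n_v, ]   # caudal-most -> cranial-most
  if (sqrt(sum(e_up^2)) < 1e-12)
    stop("sagittal_project: degenerate spine (coincident end centroids)")
  e_up <- e_up / sqrt(sum(e_up^2))
  ant <- colMeans(t(vapply(spine$vertebrae, function(v)
    proj((v$sup_ant + v$inf_ant) / 2 - (v$sup_post + v$inf_post) / 2),
    numeric(3))))
  e_ant <- ant - sum(ant * e_up) * e_up
  if (sqrt(sum(e_ant^2)) < 1e-12)
    stop("sagittal_project: cannot orient the anterior axis ",
         "(posterior->anterior directions parallel to the spine axis)")
  e_ant <- e_ant / sqrt(sum(e_ant^2))

  to2d <- function(p) { q <- proj(p); c(sum(q * e_ant), sum(q * e_up)) }
  vert2d <- lapply(spine$vertebrae, function(v) lapply(v, to2d))
  structure(list(vertebrae = vert2d, labels = spine$labels,
                 normal = normal, e_ant = e_ant, e_up = e_up),
            class = "spine_landmarks_2d")
}

#' Endplate line direction of one projected vertebra
#'
#' Unit posterior-to-anterior direction of the superior or inferior
#' endplate of a vertebra in the sagittal 2D frame.
#'
#' @param vertebra One element of a `spine_landmarks_2d` `$vertebrae`
#'   list (four length-2 corners).
#' @param which `"superior"` or `"inferior"`.
#' @return Length-2 unit vector.
#' @export
endplate_line <- function(vertebra, which = c("superior", "inferior")) {
  which <- match.arg(which)
  d <- if (which == "superior") vertebra$sup_ant - vertebra$sup_post
       else vertebra$inf_ant - vertebra$inf_post
  nd <- sqrt(sum(d^2))
  if (!is.finite(nd) || nd < 1e-12)
    stop("endplate_line: coincident ", which, " endplate corners")
  d / nd
}

#' Signed Cobb angle between two endplate lines
#'
#' Signed angle (degrees, counter-clockwise positive in the sagittal
#' frame) from line `a` to line `b`, in (-180, 180].
#'
#' @param line_a,line_b Length-2 direction vectors (need not be unit).
#' @return Angle in degrees.
#' @export
cobb_angle <- function(line_a, line_b) {
  na <- sqrt(sum(line_a^2)); nb <- sqrt(sum(line_b^2))
  if (na < 1e-12 || nb < 1e-12) stop("cobb_angle: degenerate direction")
  ang <- atan2(line_a[1L] * line_b[2L] - line_a[2L] * line_b[1L],
               sum(line_a * line_b)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  unname(ang)
}

#' Default measurement levels for CC, TTK and LL
#'
#' Standard radiographic Cobb conventions: CC between the inferior
#' endplates of C2 and C7; TTK between the superior endplate of T1 and
#' the inferior endplate of T12; LL between the superior endplates of
#' L1 and S1. `sense` sets the sign so that physiological lordosis
#' (CC, LL) and kyphosis (TTK) are reported positive.
#'
#' @return Named list of level configurations, one per angle.
#' @export
spine_levels_default <- function() {
  list(
    cc  = list(upper = c(vertebra = "C2", endplate = "inferior"),
               lower = c(vertebra = "C7", endplate = "inferior"),
               sense = "lordosis"),
    ttk = list(upper = c(vertebra = "T1", endplate = "superior"),
               lower = c(vertebra = "T12", endplate = "inferior"),
               sense = "kyphosis"),
    ll  = list(upper = c(vertebra = "L1", endplate = "superior"),
               lower = c(vertebra = "S1", endplate = "superior"),
               sense = "lordosis")
  )
}

#' Compute CC, TTK and LL spinal angles
#'
#' Projects the endplate landmarks into the intrinsic sagittal frame
#' and measures each configured angle as the signed Cobb angle between
#' its lower and upper endplate lines; lordotic curvature of the
#' cervical and lumbar regions and kyphotic curvature of the thoracic
#' region come out positive.
#'
#' @param spine A [spine_landmarks()].
#' @param levels Level configuration, default [spine_levels_default()].
#' @param plane_normal Optional sagittal plane normal (see
#'   [sagittal_project()]).
#' @return A [spine_angles()] with fields `cc`, `ttk`, `ll` (degrees).
#' @export
compute_spinal_angles <- function(spine, levels = spine_levels_default(),
                                  plane_normal = NULL) {
  s2 <- sagittal_project(spine, plane_normal)
  one <- function(cfg, what) {
    for (side in c("upper", "lower")) {
      lab <- cfg[[side]][["vertebra"]]
      if (!lab %in% s2$labels)
        stop("compute_spinal_angles: vertebra '", lab, "' required for ", what,
             " is missing from the landmark set")
    }
    u <- endplate_line(s2$vertebrae[[cfg$upper[["vertebra"]]]],
                       cfg$upper[["endplate"]])
    l <- endplate_line(s2$vertebrae[[cfg$lower[["vertebra"]]]],
                       cfg$lower[["endplate"]])
    ang <- cobb_angle(l, u)
    if (identical(cfg$sense, "kyphosis")) -ang else ang
  }
  spine_angles(cc = one(levels$cc, "CC"), ttk = one(levels$ttk, "TTK"),
               ll = one(levels$ll, "LL"))
}

#' @export
print.spine_angles <- function(x, ...) {
  cat(sprintf("spine_angles: CC %.2f deg, TTK %.2f deg, LL %.2f deg\n",
              x$cc, x$ttk, x$ll))
  invisible(x)
}
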