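# Landmark-driven smooth mesh deformation: a radial-basis-function
# interpolant with first-degree polynomial drift (the thin-plate /
# universal-Kriging-with-linear-trend interpolant) that carries a set
# of control points exactly onto a set of target points and deforms all
# other vertices smoothly with them.

.pairwise_dist <- function(a, b) {
  # ||a_i - b_j|| without forming n x m x 3 arrays
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.rbf_phi <- function(r, kernel, width) {
  switch(kernel,
         thin_plate = r,                     # biharmonic kernel in 3D
         gaussian = exp(-(r / width)^2),
         stop("unknown kernel '", kernel, "'"))
}

#' Build a landmark-driven deformation field
#'
#' Solves the RBF-plus-affine interpolation system taking every control
#' point to its same-named target point. The affine (first-degree
#' polynomial) part makes the field reproduce affine maps exactly:
#' if the targets are an affine image of the controls, every evaluated
#' point maps through that same affine. With `regularization = 0` the
#' field interpolates the targets exactly; a positive value trades
#' exactness for smoothness on noisy landmark sets.
#'
#' @param controls A [landmark_set()] of control points (mm).
#' @param targets A [landmark_set()] with the same names: where each
#'   control must land.
#' @param kernel `"thin_plate"` (default; biharmonic `r` kernel in 3D)
#'   or `"gaussian"`.
#' @param width Gaussian kernel width (mm); ignored for thin-plate.
#' @param regularization Ridge term added to the kernel diagonal
#'   (>= 0, default 0 = exact interpolation).
#' @return An object of class `deformation_field`.
#' @export
build_field <- function(controls, targets, kernel = c("thin_plate", "gaussian"),
                        width = NULL, regularization = 0) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(controls, "landmark_set"), inherits(targets, "landmark_set"))
  if (!identical(sort(controls$names), sort(targets$names)))
    stop("build_field: control and target landmark names differ")
  if (regularization < 0) stop("build_field: regularization must be >= 0")
  if (kernel == "gaussian") {
    if (is.null(width) || !is.finite(width) || width <= 0)
      stop("build_field: gaussian kernel needs a positive width")
  } else width <- NA_real_

  C <- controls$coords
  Tm <- targets$coords[controls$names, , drop = FALSE]
  n <- nrow(C)
  if (n < 4L)
    stop("build_field: at least 4 control points are needed for a 3D field")
  D <- .pairwise_dist(C, C)
  dup <- which(D < 1e-9 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup))
    stop("build_field: duplicate control points: ",
         paste(apply(dup, 1L, function(ij)
           paste0("'", controls$names[ij[1L]], "'/'", controls$names[ij[2L]], "'")),
           collapse = ", "))
  P <- cbind(1, C)                             # n x 4 polynomial basis
  if (qr(P)$rank < 4L)
    stop("build_field: control points are coplanar; the 3D polynomial ",
         "drift is ill-posed (need at least 4 non-coplanar landmarks)")
  K <- .rbf_phi(D, kernel, width)
  M <- rbind(cbind(K + diag(regularization, n), P),
             cbind(t(P), matrix(0, 4L, 4L)))
  cond <- kappa(M, exact = FALSE)
  if (is.finite(cond) && cond > 1e12)
    warning("build_field: interpolation system is ill-conditioned ",
            "(condition estimate ", format(cond, digits = 3), ")")
  sol <- solve(M, rbind(Tm, matrix(0, 4L, 3L)))
  structure(list(kernel = kernel, width = width,
                 control_points = controls,
                 targets = landmark_set(controls$names, Tm),
                 rbf_weights = sol[seq_len(n), , drop = FALSE],
                 affine_part = sol[n + 1:4, , drop = FALSE],
                 regularization = regularization),
            class = "deformation_field")
}

#' Evaluate a deformation field at arbitrary points
#'
#' @param field A [build_field()] result.
#' @param points n x 3 numeric matrix (mm).
#' @return n x 3 matrix of mapped points.
#' @export
evaluate_field <- function(field, points) {
  stopifnot(inherits(field, "deformation_field"))
  points <- as.matrix(points)
  K <- .rbf_phi(.pairwise_dist(points, field$control_points$coords),
                field$kernel, field$width)
  out <- cbind(1, points) %*% field$affine_part + K %*% field$rbf_weights
  dimnames(out) <- NULL
  out
}

#' Morph a mesh through a deformation field
#'
#' Maps every vertex through the field; faces are carried over
#' unchanged.
#'
#' @param mesh A [point_cloud()] (optionally with faces).
#' @param field A [build_field()] result.
#' @return The morphed [point_cloud()].
#' @export
apply_field <- function(mesh, field) {
  stopifnot(inherits(mesh, "point_cloud"))
  point_cloud(evaluate_field(field, mesh$points), mesh$faces)
}

#' Worst left/right mismatch of a mirror-paired landmark set
#'
#' For each declared left/right pair, reflects the right landmark
#' through the sagittal plane and measures its distance to the left
#' one; midline landmarks (paired with themselves) are measured against
#' their own reflection. Returns the worst mismatch in mm.
#'
#' @param lm A [landmark_set()].
#' @param pairs Two-column character matrix of (left, right) landmark
#'   names; use the same name in both columns for midline landmarks.
#' @param plane_point A point on the sagittal plane (default origin).
#' @param plane_normal Unit normal of the sagittal plane (default
#'   `c(1, 0, 0)`).
#' @return Maximum mismatch (mm), with per-pair values as the
#'   `"per_pair"` attribute.
#' @export
symmetry_check <- function(lm, pairs, plane_point = c(0, 0, 0),
                           plane_normal = c(1, 0, 0)) {
  stopifnot(inherits(lm, "landmark_set"))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("symmetry_check: pairs must be a 2-column matrix")
  missing <- setdiff(unique(c(pairs)), lm$names)
  if (length(missing))
    stop("symmetry_check: unpaired/unknown landmark(s): ",
         paste(missing, collapse = ", "))
  n <- as.numeric(plane_normal); n <- n / sqrt(sum(n^2))
  p0 <- as.numeric(plane_point)
  reflect <- function(x) x - 2 * sum((x - p0) * n) * n
  d <- apply(pairs, 1L, function(pr) {
    l <- lm$coords[pr[1L], ]; r <- lm$coords[pr[2L], ]
    sqrt(sum((l - reflect(r))^2))
  })
  names(d) <- paste(pairs[, 1L], pairs[, 2L], sep = "|")
  structure(max(d), per_pair = d)
}
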