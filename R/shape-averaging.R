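# Mean body-shape construction: RBF landmark correspondence between
# scans, orthogonal (proper-rotation) Procrustes alignment via SVD, and
# generalized Procrustes iteration to a converging mean shape.

#' Establish point-to-point correspondence between two scans
#'
#' Warps the base cloud by the RBF deformation field taking the base
#' landmarks onto the target landmarks, then snaps each warped base
#' point to its nearest neighbour on the target cloud. The result has
#' the base's point count and ordering, so a set of scans corresponded
#' to one base becomes homologous and can be averaged point-wise.
#' Nearest-neighbour ties are broken toward the lowest target index.
#'
#' @param base A [point_cloud()], the reference topology.
#' @param base_lm,target_lm [landmark_set()]s sharing names (the
#'   classical use has 69 manually placed landmarks).
#' @param target A [point_cloud()] to bring into correspondence.
#' @param kernel,width,regularization Passed to [build_field()].
#' @return A [point_cloud()] with `nrow(base$points)` points sampled
#'   from `target`, in base ordering; faces copied from the base.
#' @export
correspond <- function(base, base_lm, target, target_lm,
                       kernel = "thin_plate", width = NULL,
                       regularization = 0) {
  stopifnot(inherits(base, "point_cloud"), inherits(target, "point_cloud"))
  field <- build_field(base_lm, target_lm, kernel = kernel, width = width,
                       regularization = regularization)
  warped <- evaluate_field(field, base$points)
  idx <- .nearest_index(warped, target$points)
  point_cloud(target$points[idx, , drop = FALSE], base$faces)
}

# index of the nearest target point for each query point; ties -> lowest
# index (max.col with ties.method = "first" on negated distances)
.nearest_index <- function(query, target, chunk = 2048L) {
  n <- nrow(query)
  idx <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(rowSums(query[s:e, , drop = FALSE]^2), rowSums(target^2), "+") -
      2 * tcrossprod(query[s:e, , drop = FALSE], target)
    idx[s:e] <- max.col(-d2, ties.method = "first")
  }
  idx
}

#' Optimal proper rotation between two homologous clouds
#'
#' Centers both clouds and returns the proper rotation R (and implied
#' translation) minimizing the Frobenius norm of `(X - c_X) R -
#' (Xbar - c_Xbar)`, solved through the singular value decomposition of
#' the cross-covariance with determinant sign correction, so the body
#' is never mirrored. No scaling is applied. When the smallest singular
#' value is (near) zero the reflection correction flips that axis,
#' which is the deterministic tie-break for degenerate spectra.
#'
#' @param x,xbar [point_cloud()]s or n x 3 matrices with equal point
#'   counts (n >= 3 non-collinear).
#' @return A list with `rotation` (3 x 3, `det = +1`), `translation`
#'   (length 3; `x %*% R + t` best matches `xbar`), `objective` (the
#'   minimized squared Frobenius norm), and `degenerate` (logical:
#'   rank-deficient cross-covariance).
#' @export
orthogonal_align <- function(x, xbar) {
  X <- if (inherits(x, "point_cloud")) x$points else as.matrix(x)
  Y <- if (inherits(xbar, "point_cloud")) xbar$points else as.matrix(xbar)
  if (nrow(X) != nrow(Y))
    stop("orthogonal_align: point counts differ (", nrow(X), " vs ", nrow(Y), ")")
  if (nrow(X) < 3L) stop("orthogonal_align: need at least 3 points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  H <- crossprod(Xc, Yc)                       # X^T Y cross-covariance
  sv <- svd(H)
  s <- c(1, 1, sign(det(tcrossprod(sv$u, sv$v))))
  if (s[3L] == 0) s[3L] <- 1                   # fully degenerate: identity flip
  R <- sv$u %*% diag(s) %*% t(sv$v)
  degenerate <- sv$d[3L] < max(sv$d[1L], 1) * 1e-12
  obj <- sum((Xc %*% R - Yc)^2)
  list(rotation = R, translation = drop(cy - cx %*% R),
       objective = obj, degenerate = degenerate)
}

#' Generalized Procrustes mean shape of corresponded clouds
#'
#' Iteratively aligns every cloud to the current mean by
#' [orthogonal_align()] and recomputes the mean as the point-wise
#' average, until the relative change of the total objective
#' `sum_g ||X_g R_g + t_g - mean||^2` drops below `tol` or `max_iter`
#' is reached. The first cloud seeds the mean and the result is
#' reported rigidly aligned back onto the first cloud's frame.
#'
#' @param clouds List of >= 2 homologous [point_cloud()]s (equal point
#'   counts and ordering, e.g. from [correspond()]).
#' @param tol Relative objective-change stopping tolerance.
#' @param max_iter Iteration cap.
#' @return A list of class `alignment_result`: `mean_shape`
#'   ([point_cloud()]), `rotations`, `translations` (per cloud, mapping
#'   it onto the mean), `objective_trace` (per-iteration objective,
#'   non-increasing), `iterations`, `converged`.
#' @export
mean_shape <- function(clouds, tol = 1e-6, max_iter = 100L) {
  if (length(clouds) < 2L) stop("mean_shape: need at least 2 clouds")
  mats <- lapply(clouds, function(cl) {
    if (inherits(cl, "point_cloud")) cl$points else as.matrix(cl)
  })
  np <- vapply(mats, nrow, integer(1))
  if (length(unique(np)) != 1L)
    stop("mean_shape: clouds are not corresponded (point counts ",
         paste(unique(np), collapse = ", "), ")")
  base <- mats[[1L]]
  mean_cur <- base
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    aligned <- lapply(mats, function(X) {
      a <- orthogonal_align(X, mean_cur)
      sweep(X %*% a$rotation, 2L, a$translation, "+")
    })
    mean_cur <- Reduce(`+`, aligned) / length(aligned)
    obj <- sum(vapply(aligned, function(A) sum((A - mean_cur)^2), numeric(1)))
    trace <- c(trace, obj)
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (prev <= .Machine$double.eps || (prev - obj) / prev < tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("mean_shape: not converged after ", max_iter, " iterations")
  # report the mean in the first (base) cloud's frame
  a0 <- orthogonal_align(mean_cur, base)
  mean_final <- sweep(mean_cur %*% a0$rotation, 2L, a0$translation, "+")
  fits <- lapply(mats, orthogonal_align, xbar = mean_final)
  faces <- if (inherits(clouds[[1L]], "point_cloud")) clouds[[1L]]$faces else NULL
  structure(list(
    mean_shape = point_cloud(mean_final, faces),
    rotations = lapply(fits, `[[`, "rotation"),
    translations = lapply(fits, `[[`, "translation"),
    objective_trace = trace,
    iterations = length(trace),
    converged = converged
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result: %d clouds, %d iterations (%sconverged), final objective %.4g\n",
              length(x$rotations), x$iterations,
              if (x$converged) "" else "NOT ", utils::tail(x$objective_trace, 1L)))
  invisible(x)
}
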