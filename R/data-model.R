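# Shared domain types for the seat-comfort pipeline. All constructors
# validate their invariants and fail with messages naming the offending
# record, so downstream code can assume well-formed objects.

#' Canonical cranio-caudal vertebra sequence
#'
#' Ordered vertebra labels from C1 down to S1. Spine landmark sets must
#' list their vertebrae as a subsequence of this ordering.
#'
#' @return Character vector of vertebra labels.
#' @export
vertebra_sequence <- function() {
  c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5), "S1")
}

#' Pressure map: rectangular grid of interface pressures
#'
#' The unit of all surface-comfort computation: a rows x cols grid of
#' cell pressures in kPa as exported by a capacitive pressure mat, with
#' the physical cell pitch and the body-seat interface it was recorded
#' at. A value of 0 means "no contact"; negative pressures are invalid.
#'
#' @param grid Numeric matrix of pressures (kPa), all finite and >= 0.
#' @param cell_pitch Length-2 numeric, physical size of one cell in mm
#'   (row pitch, column pitch); both > 0.
#' @param interface `"cushion"` or `"backrest"`.
#' @param origin_note Free text describing the orientation of row 0
#'   (metadata only; metrics are orientation-invariant).
#' @return An object of class `pressure_map`.
#' @examples
#' pm <- pressure_map(matrix(c(0, 1, 2, 3), 2, byrow = TRUE),
#'                    cell_pitch = c(10, 10), interface = "cushion")
#' dim(pm$grid)
#' @export
pressure_map <- function(grid, cell_pitch, interface = c("cushion", "backrest"),
                         origin_note = "row 1 = top of mat as exported") {
  interface <- match.arg(interface)
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  if (nrow(grid) < 1L || ncol(grid) < 1L)
    stop("pressure_map: grid must have at least one row and one column")
  if (any(!is.finite(grid)))
    stop("pressure_map: non-finite pressure at cell (",
         paste(which(!is.finite(grid), arr.ind = TRUE)[1L, ], collapse = ","), ")")
  if (any(grid < 0)) {
    bad <- which(grid < 0, arr.ind = TRUE)[1L, ]
    stop("pressure_map: negative pressure ", grid[bad[1L], bad[2L]],
         " kPa at cell (", bad[1L], ",", bad[2L], ")")
  }
  cell_pitch <- as.numeric(cell_pitch)
  if (length(cell_pitch) != 2L || any(!is.finite(cell_pitch)) || any(cell_pitch <= 0))
    stop("pressure_map: cell_pitch must be two positive values (mm)")
  structure(
    list(grid = grid, cell_pitch = cell_pitch, interface = interface,
         origin_note = as.character(origin_note)[1L]),
    class = "pressure_map"
  )
}

#' @export
print.pressure_map <- function(x, ...) {
  cat(sprintf("pressure_map: %d x %d cells, pitch %g x %g mm, interface '%s'\n",
              nrow(x$grid), ncol(x$grid), x$cell_pitch[1L], x$cell_pitch[2L],
              x$interface))
  cat(sprintf("  range [%g, %g] kPa, %d cells > 0\n",
              min(x$grid), max(x$grid), sum(x$grid > 0)))
  invisible(x)
}

#' Region mask over a pressure map
#'
#' A named set of (row, col) cell indices selecting one anatomical
#' region of a pressure map (hip, legs, waist, back, or the whole mat).
#'
#' @param name One of `"hip"`, `"legs"`, `"waist"`, `"back"`, `"whole"`.
#' @param cells Two-column integer matrix of (row, col) indices, or
#'   `NULL` for an empty mask.
#' @param map Optional `pressure_map`; when given, indices are checked
#'   against its bounds.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(name = c("hip", "legs", "waist", "back", "whole"),
                        cells, map = NULL) {
  name <- match.arg(name)
  if (is.null(cells) || (is.matrix(cells) && nrow(cells) == 0L)) {
    cells <- matrix(integer(0), ncol = 2L)
  } else {
    cells <- as.matrix(cells)
    if (ncol(cells) != 2L)
      stop("region_mask: cells must be a two-column (row, col) matrix")
    storage.mode(cells) <- "integer"
    if (anyDuplicated(cells))
      stop("region_mask '", name, "': duplicate cell indices")
  }
  colnames(cells) <- c("row", "col")
  if (!is.null(map)) {
    if (!inherits(map, "pressure_map")) stop("map must be a pressure_map")
    if (nrow(cells) && (any(cells[, 1L] < 1L) || any(cells[, 1L] > nrow(map$grid)) ||
                        any(cells[, 2L] < 1L) || any(cells[, 2L] > ncol(map$grid))))
      stop("region_mask '", name, "': cell indices outside the ",
           nrow(map$grid), " x ", ncol(map$grid), " grid")
  }
  structure(list(name = name, cells = cells), class = "region_mask")
}

#' Whole-map region mask
#'
#' @param map A `pressure_map`.
#' @return A `region_mask` named `"whole"` covering every cell.
#' @export
whole_region <- function(map) {
  stopifnot(inherits(map, "pressure_map"))
  idx <- as.matrix(expand.grid(row = seq_len(nrow(map$grid)),
                               col = seq_len(ncol(map$grid))))
  region_mask("whole", idx, map)
}

#' Named 3D landmark set
#'
#' Ordered named points in mm, e.g. the 69-point sets used for
#' point-cloud averaging or the 142 symmetrical control points used for
#' mesh morphing.
#'
#' @param names Character vector of unique landmark identifiers.
#' @param coords Numeric n x 3 matrix of coordinates (mm), finite.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(names, coords) {
  names <- as.character(names)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("landmark_set: coords must be an n x 3 matrix")
  if (length(names) != nrow(coords))
    stop("landmark_set: ", length(names), " names but ", nrow(coords), " points")
  dup <- names[duplicated(names)]
  if (length(dup))
    stop("landmark_set: duplicate landmark name(s): ",
         paste(unique(dup), collapse = ", "))
  if (any(!is.finite(coords))) {
    bad <- names[which(rowSums(!is.finite(coords)) > 0)[1L]]
    stop("landmark_set: non-finite coordinates for landmark '", bad, "'")
  }
  rownames(coords) <- names
  colnames(coords) <- c("x", "y", "z")
  structure(list(names = names, coords = coords), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:", length(x$names), "landmarks\n")
  invisible(x)
}

#' Point cloud / triangle surface mesh
#'
#' An ordered set of 3D points in mm, optionally with triangle faces
#' (making it a surface mesh). Homologous clouds (same point count and
#' ordering) are the input to shape averaging.
#'
#' @param points Numeric n x 3 matrix (mm), finite.
#' @param faces Optional integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, faces = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("point_cloud: points must be n x 3")
  if (any(!is.finite(points)))
    stop("point_cloud: non-finite coordinate at point ",
         which(rowSums(!is.finite(points)) > 0)[1L])
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    if (ncol(faces) != 3L) stop("point_cloud: faces must be m x 3 triangles")
    if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(points)))
      stop("point_cloud: face index ", max(max(faces), 0L),
           " outside vertex range 1..", nrow(points))
  }
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, faces = faces), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", nrow(x$points),
              if (is.null(x$faces)) "" else sprintf(", %d faces", nrow(x$faces))))
  invisible(x)
}

.spine_roles <- c("sup_ant", "sup_post", "inf_ant", "inf_post")

#' Vertebral endplate landmark set
#'
#' Per-vertebra endplate corner points in mm from which sagittal Cobb
#' angles are computed. Each vertebra carries the four corners of its
#' superior and inferior endplates: `sup_ant`, `sup_post`, `inf_ant`,
#' `inf_post`. Vertebrae must be listed in strict cranio-caudal order
#' (a subsequence of [vertebra_sequence()]).
#'
#' @param vertebrae Named list; each element is a list with the four
#'   corner points, each a finite length-3 numeric (mm). Names are the
#'   vertebra labels (e.g. `"L1"`).
#' @return An object of class `spine_landmarks`.
#' @export
spine_landmarks <- function(vertebrae) {
  labels <- names(vertebrae)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("spine_landmarks: vertebrae must be a named list of labels")
  seq_all <- vertebra_sequence()
  pos <- match(labels, seq_all)
  if (anyNA(pos))
    stop("spine_landmarks: unknown vertebra label(s): ",
         paste(labels[is.na(pos)], collapse = ", "))
  if (is.unsorted(pos, strictly = TRUE))
    stop("spine_landmarks: labels must be strictly ordered cranio-caudally (",
         paste(seq_all[range(pos)], collapse = "..."), ")")
  vertebrae <- lapply(seq_along(vertebrae), function(i) {
    v <- vertebrae[[i]]
    for (role in .spine_roles) {
      p <- v[[role]]
      if (is.null(p))
        stop("spine_landmarks: vertebra '", labels[i], "' is missing corner '",
             role, "'")
      p <- as.numeric(p)
      if (length(p) != 3L || any(!is.finite(p)))
        stop("spine_landmarks: vertebra '", labels[i], "', corner '", role,
             "' must be a finite 3D point")
      v[[role]] <- p
    }
    v[.spine_roles]
  })
  names(vertebrae) <- labels
  structure(list(vertebrae = vertebrae, labels = labels),
            class = "spine_landmarks")
}

#' @export
print.spine_landmarks <- function(x, ...) {
  cat("spine_landmarks:", length(x$labels), "vertebrae (",
      x$labels[1L], "...", x$labels[length(x$labels)], ")\n")
  invisible(x)
}

#' Sagittal spinal angle triple
#'
#' @param cc Cervical lordosis (degrees, lordosis positive).
#' @param ttk Thoracic kyphosis (degrees, kyphosis positive).
#' @param ll Lumbar lordosis (degrees, lordosis positive).
#' @return An object of class `spine_angles`.
#' @export
spine_angles <- function(cc, ttk, ll) {
  a <- c(cc = as.numeric(cc), ttk = as.numeric(ttk), ll = as.numeric(ll))
  if (any(!is.finite(a)) || any(a <= -90) || any(a >= 180))
    stop("spine_angles: angles must be finite and in (-90, 180) degrees")
  structure(as.list(a), class = "spine_angles")
}

#' Low-density foam material parameter set
#'
#' Houses the parameters of the hysteretic foam point model: density,
#' tensile elastic modulus, the monotone compressive loading curve, the
#' hysteretic unloading coefficient HU, the unloading shape factor
#' SHAPE, and the creep decay constant BETA (stored but unused in the
#' quasi-static mode this package implements).
#'
#' @param ro Density, kg/m^3 (> 0).
#' @param e Tensile elastic modulus, MPa (> 0).
#' @param load_curve Two-column matrix (engineering strain, stress MPa);
#'   must pass through (0, 0) and be non-decreasing in both columns.
#' @param hu Hysteretic unloading coefficient in (0, 1].
#' @param shape Unloading shape factor > 0.
#' @param beta Creep decay constant >= 0 (default 0).
#' @return An object of class `foam_params`.
#' @export
foam_params <- function(ro, e, load_curve, hu, shape, beta = 0) {
  load_curve <- as.matrix(load_curve)
  storage.mode(load_curve) <- "double"
  if (ncol(load_curve) != 2L || nrow(load_curve) < 2L)
    stop("foam_params: load_curve must be an n x 2 (strain, stress) matrix, n >= 2")
  colnames(load_curve) <- c("strain", "stress")
  if (any(!is.finite(load_curve)))
    stop("foam_params: non-finite load_curve entry")
  if (abs(load_curve[1L, 1L]) > 1e-12 || abs(load_curve[1L, 2L]) > 1e-12)
    stop("foam_params: load_curve must start at (0, 0), got (",
         load_curve[1L, 1L], ", ", load_curve[1L, 2L], ")")
  if (any(diff(load_curve[, 1L]) <= 0))
    stop("foam_params: load_curve strains must be strictly increasing")
  if (any(diff(load_curve[, 2L]) < 0))
    stop("foam_params: load_curve stresses must be non-decreasing")
  if (!is.finite(hu) || hu <= 0 || hu > 1)
    stop("foam_params: hu must be in (0, 1], got ", hu)
  if (!is.finite(shape) || shape <= 0)
    stop("foam_params: shape must be > 0, got ", shape)
  if (!is.finite(beta) || beta < 0)
    stop("foam_params: beta must be >= 0, got ", beta)
  if (!is.finite(ro) || ro <= 0) stop("foam_params: ro must be > 0")
  if (!is.finite(e) || e <= 0) stop("foam_params: e must be > 0")
  structure(list(ro = as.numeric(ro), e = as.numeric(e),
                 load_curve = load_curve, hu = as.numeric(hu),
                 shape = as.numeric(shape), beta = as.numeric(beta)),
            class = "foam_params")
}

#' Uniaxial foam load-unload test record
#'
#' One loading branch from 0 up to the maximum strain followed by one
#' unloading branch back toward 0, with the measured stress at each
#' strain sample.
#'
#' @param strain Ordered engineering strains along the path (load then
#'   unload; piecewise monotone).
#' @param stress Measured stress (MPa) per strain sample, all >= 0.
#' @param noise_sd Measurement noise standard deviation (MPa), metadata.
#' @return An object of class `uniaxial_test`.
#' @export
uniaxial_test <- function(strain, stress, noise_sd = 0) {
  strain <- as.numeric(strain); stress <- as.numeric(stress)
  if (length(strain) != length(stress) || length(strain) < 3L)
    stop("uniaxial_test: strain and stress must be equal length >= 3")
  if (any(!is.finite(strain)) || any(!is.finite(stress)))
    stop("uniaxial_test: non-finite sample")
  if (any(stress < 0)) stop("uniaxial_test: negative stress sample")
  i_max <- which.max(strain)
  load_ok <- i_max == 1L || all(diff(strain[1:i_max]) > 0)
  unload_ok <- i_max == length(strain) || all(diff(strain[i_max:length(strain)]) < 0)
  if (!load_ok || !unload_ok)
    stop("uniaxial_test: strain path must be one monotone loading branch ",
         "followed by one monotone unloading branch")
  structure(list(strain = strain, stress = stress, i_max = i_max,
                 noise_sd = as.numeric(noise_sd)),
            class = "uniaxial_test")
}

#' Single seat-configuration analysis result
#'
#' Bundles the per-region surface pressure metrics for one seat
#' adjustment condition (a whole-chair flip angle or a backrest flip
#' angle), with optional internal-response values supplied by an
#' external solver and optional spinal angles.
#'
#' @param condition_kind `"whole_chair_flip"` or `"backrest_flip"`.
#' @param angle Adjustment angle, degrees.
#' @param region_metrics Named list of `pressure_metrics` (one per
#'   region of a partition).
#' @param internal Optional named list with any of `vertebral_max_stress`
#'   (MPa), `disc_max_stress` (MPa), `disc_max_strain` (dimensionless).
#' @param spine Optional `spine_angles`.
#' @param comfort Optional named list of comfort classifications.
#' @return An object of class `condition_result`.
#' @export
condition_result <- function(condition_kind = c("whole_chair_flip", "backrest_flip"),
                             angle, region_metrics, internal = NULL,
                             spine = NULL, comfort = NULL) {
  condition_kind <- match.arg(condition_kind)
  if (!is.finite(angle)) stop("condition_result: angle must be finite")
  if (!length(region_metrics) || is.null(names(region_metrics)))
    stop("condition_result: region_metrics must be a named list")
  structure(list(condition_kind = condition_kind, angle = as.numeric(angle),
                 region_metrics = region_metrics, internal = internal,
                 spine = spine, comfort = comfort),
            class = "condition_result")
}
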