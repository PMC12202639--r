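# Seeded synthetic-data generators emulating the statistical structure
# of a human-seat comfort study's inputs: pressure-mat exports, sagittal
# spines with prescribed curvature, families of body scans around a
# known mean shape, foam load-unload tests, and multi-angle condition
# series. Every generator is a pure function of its arguments including
# the seed (the caller's RNG state is untouched).

#' Pressure-map generation scenario
#'
#' Describes one synthetic mat recording: grid size and pitch, the
#' interface, exponential-decay pressure peaks, the elliptical contact
#' patch, and the noise level.
#'
#' @param interface `"cushion"` or `"backrest"`.
#' @param nrow,ncol Grid dimensions (cells).
#' @param cell_pitch Length-2 cell pitch (mm).
#' @param peak_centers k x 2 matrix of (row, col) peak positions
#'   (within the grid).
#' @param peak_amplitudes Peak pressures (kPa, > 0), one per peak.
#' @param decay_length Exponential decay length (cells, > 0).
#' @param noise_sd Gaussian noise SD (kPa) inside the contact patch.
#' @param ellipse_center,ellipse_semi (row, col) center and semi-axes
#'   (cells) of the contact ellipse.
#' @param seed Mandatory integer seed.
#' @return An object of class `pressure_scenario`.
#' @export
pressure_scenario <- function(interface = c("cushion", "backrest"),
                              nrow = 40L, ncol = 32L, cell_pitch = c(12.7, 12.7),
                              peak_centers, peak_amplitudes, decay_length = 5,
                              noise_sd = 0.3, ellipse_center, ellipse_semi,
                              seed) {
  interface <- match.arg(interface)
  peak_centers <- matrix(as.numeric(peak_centers), ncol = 2L)
  if (missing(seed) || is.null(seed)) stop("pressure_scenario: seed is mandatory")
  if (any(peak_amplitudes <= 0)) stop("pressure_scenario: amplitudes must be > 0")
  if (length(peak_amplitudes) != nrow(peak_centers))
    stop("pressure_scenario: one amplitude per peak center")
  if (decay_length <= 0) stop("pressure_scenario: decay_length must be > 0")
  if (any(peak_centers[, 1L] < 1) || any(peak_centers[, 1L] > nrow) ||
      any(peak_centers[, 2L] < 1) || any(peak_centers[, 2L] > ncol))
    stop("pressure_scenario: peak center outside the ", nrow, " x ", ncol, " grid")
  structure(list(interface = interface, nrow = as.integer(nrow),
                 ncol = as.integer(ncol), cell_pitch = cell_pitch,
                 peak_centers = peak_centers,
                 peak_amplitudes = as.numeric(peak_amplitudes),
                 decay_length = as.numeric(decay_length),
                 noise_sd = as.numeric(noise_sd),
                 ellipse_center = as.numeric(ellipse_center),
                 ellipse_semi = as.numeric(ellipse_semi),
                 seed = as.integer(seed)),
            class = "pressure_scenario")
}

#' Default cushion scenario: two ischial-tuberosity peaks
#'
#' Two pressure peaks at the ischial tuberosities near the rear of the
#' cushion, decaying exponentially along the thighs, inside an
#' elongated contact ellipse. Default amplitudes put the cushion
#' maximum inside the 7-11 kPa ideal band.
#'
#' @param seed Integer seed.
#' @param peak_kpa Peak amplitude (kPa) of each tuberosity bump (the
#'   map maximum lands somewhat higher where the two bumps overlap).
#' @param noise_sd Noise SD (kPa).
#' @param ellipse_semi Contact-ellipse semi-axes (cells).
#' @return A [pressure_scenario()].
#' @export
cushion_scenario <- function(seed, peak_kpa = 8, noise_sd = 0.3,
                             ellipse_semi = c(17, 11)) {
  pressure_scenario("cushion", nrow = 40L, ncol = 32L,
                    peak_centers = rbind(c(12, 13), c(12, 20)),
                    peak_amplitudes = c(peak_kpa, peak_kpa),
                    decay_length = 4, noise_sd = noise_sd,
                    ellipse_center = c(20, 16.5), ellipse_semi = ellipse_semi,
                    seed = seed)
}

#' Default backrest scenario: mid-waist peak
#'
#' A single peak at the middle of the waist, decaying toward the
#' periphery of the backrest contact patch; the default amplitude puts
#' the waist maximum inside the 4-8 kPa ideal band.
#'
#' @inheritParams cushion_scenario
#' @return A [pressure_scenario()].
#' @export
backrest_scenario <- function(seed, peak_kpa = 6, noise_sd = 0.3,
                              ellipse_semi = c(16, 10)) {
  pressure_scenario("backrest", nrow = 40L, ncol = 32L,
                    peak_centers = rbind(c(27, 16.5)),
                    peak_amplitudes = peak_kpa,
                    decay_length = 6, noise_sd = noise_sd,
                    ellipse_center = c(22, 16.5), ellipse_semi = ellipse_semi,
                    seed = seed)
}

#' Generate a synthetic pressure map
#'
#' Sums isotropic exponential-decay bumps at the scenario's peak
#' centers, clips the field to the elliptical contact patch, and adds
#' zero-truncated Gaussian noise inside the patch. Deterministic for a
#' given scenario (the seed is part of it).
#'
#' @param scenario A [pressure_scenario()].
#' @return A [pressure_map()].
#' @export
gen_pressure_map <- function(scenario) {
  stopifnot(inherits(scenario, "pressure_scenario"))
  s <- scenario
  rows <- matrix(seq_len(s$nrow), s$nrow, s$ncol)
  cols <- matrix(seq_len(s$ncol), s$nrow, s$ncol, byrow = TRUE)
  base <- 0
  for (k in seq_len(nrow(s$peak_centers))) {
    d <- sqrt((rows - s$peak_centers[k, 1L])^2 + (cols - s$peak_centers[k, 2L])^2)
    base <- base + s$peak_amplitudes[k] * exp(-d / s$decay_length)
  }
  inside <- ((rows - s$ellipse_center[1L]) / s$ellipse_semi[1L])^2 +
            ((cols - s$ellipse_center[2L]) / s$ellipse_semi[2L])^2 <= 1
  grid <- .with_seed(s$seed, {
    noise <- matrix(stats::rnorm(s$nrow * s$ncol, 0, s$noise_sd), s$nrow, s$ncol)
    pmax(base + noise, 0) * inside
  })
  pressure_map(grid, s$cell_pitch, s$interface,
               origin_note = "synthetic; row 1 = top of mat")
}

#' Generate spine landmarks with prescribed sagittal angles
#'
#' Builds a sagittal chain of quadrilateral vertebra profiles
#' (C2...S1) whose endplate tilts realize exactly the requested
#' cervical lordosis, thoracic kyphosis and lumbar lordosis under the
#' default measurement levels of [spine_levels_default()]: within each
#' region the endplate tilt varies linearly between the region's
#' bounding vertebrae. Endplates are parallel within a vertebra.
#' Optional isotropic Gaussian jitter perturbs every corner.
#'
#' @param cc,ttk,ll Target angles (degrees, magnitudes < 90).
#' @param vertebra_height,vertebra_depth,disc_gap Body height, sagittal
#'   depth and inter-vertebral gap (mm); scalars or per-vertebra.
#' @param jitter_sd Corner jitter SD (mm), default 0.
#' @param seed Seed for the jitter (required when `jitter_sd > 0`).
#' @return A [spine_landmarks()] embedded in the x = 0 sagittal plane
#'   (y anterior, z cranial).
#' @export
gen_spine <- function(cc, ttk, ll, vertebra_height = NULL, vertebra_depth = NULL,
                      disc_gap = 5, jitter_sd = 0, seed = NULL) {
  if (max(abs(c(cc, ttk, ll))) >= 90)
    stop("gen_spine: angle magnitudes must be < 90 degrees")
  if (jitter_sd > 0 && is.null(seed))
    stop("gen_spine: jitter needs a seed")
  labels <- c(paste0("C", 2:7), paste0("T", 1:12), paste0("L", 1:5), "S1")
  nv <- length(labels)
  region <- c(rep("cervical", 6L), rep("thoracic", 12L), rep("lumbar", 6L))
  if (is.null(vertebra_height))
    vertebra_height <- c(cervical = 14, thoracic = 20, lumbar = 27)[region]
  if (is.null(vertebra_depth))
    vertebra_depth <- c(cervical = 16, thoracic = 26, lumbar = 33)[region]
  h <- rep_len(vertebra_height, nv); D <- rep_len(vertebra_depth, nv)
  gap <- rep_len(disc_gap, nv)

  # endplate tilt per vertebra (degrees), cranial -> caudal order;
  # linear within each region so the bounding differences are exact
  th <- numeric(nv)
  i_lum <- which(region == "lumbar")            # L1..S1
  i_tho <- which(region == "thoracic")          # T1..T12
  i_cer <- which(region == "cervical")          # C2..C7
  th[i_lum] <- seq(ll / 2, -ll / 2, length.out = length(i_lum))      # L1 -> S1
  th_T12 <- th[i_lum[1L]]                       # continuity at the junction
  th[i_tho] <- seq(th_T12 - ttk, th_T12, length.out = length(i_tho)) # T1 -> T12
  th_C7 <- th[i_tho[1L]]
  th[i_cer] <- seq(th_C7 + cc, th_C7, length.out = length(i_cer))    # C2 -> C7

  # walk the chain caudal -> cranial in the (anterior, cranial) plane
  thr <- th * pi / 180
  d2 <- cbind(cos(thr), sin(thr))               # endplate direction
  n2 <- cbind(-sin(thr), cos(thr))              # cranial normal
  ctr <- matrix(NA_real_, nv, 2L)
  ctr[nv, ] <- c(0, 0)
  for (i in (nv - 1L):1L) {
    ctr[i, ] <- ctr[i + 1L, ] + (h[i + 1L] / 2 + gap[i]) * n2[i + 1L, ] +
      (h[i] / 2) * n2[i, ]
    if (sum((ctr[i, ] - ctr[i + 1L, ]) * n2[i + 1L, ]) <= h[i + 1L] / 2)
      stop("gen_spine: infeasible geometry (vertebra ", labels[i],
           " overlaps ", labels[i + 1L], ")")
  }
  embed <- function(p2) c(0, p2[1L], p2[2L])    # sagittal plane x = 0
  vert <- lapply(seq_len(nv), function(i) {
    list(sup_ant  = embed(ctr[i, ] + (h[i] / 2) * n2[i, ] + (D[i] / 2) * d2[i, ]),
         sup_post = embed(ctr[i, ] + (h[i] / 2) * n2[i, ] - (D[i] / 2) * d2[i, ]),
         inf_ant  = embed(ctr[i, ] - (h[i] / 2) * n2[i, ] + (D[i] / 2) * d2[i, ]),
         inf_post = embed(ctr[i, ] - (h[i] / 2) * n2[i, ] - (D[i] / 2) * d2[i, ]))
  })
  names(vert) <- labels
  if (jitter_sd > 0) {
    vert <- .with_seed(seed, lapply(vert, function(v)
      lapply(v, function(p) p + stats::rnorm(3L, 0, jitter_sd))))
  }
  spine_landmarks(vert)
}

#' Generate a family of body scans around a known mean
#'
#' Emulates surface scans of several volunteers: each subject is the
#' template warped by a random smooth Gaussian-RBF displacement field
#' (the fields are constrained to zero mean across subjects, so the
#' template is exactly the true mean pre-rotation), then rigidly
#' rotated by a random rotation of at most `rot_amp` degrees, with
#' Gaussian coordinate noise added to the cloud (landmarks are carried
#' through the warp and rotation noise-free).
#'
#' @param template A [point_cloud()], the true mean shape.
#' @param template_lm A [landmark_set()] on the template.
#' @param n_subjects Number of subjects (>= 2; the classical study uses 4).
#' @param deform_amp Approximate peak smooth-deformation amplitude (mm).
#' @param rot_amp Maximum rigid rotation (degrees).
#' @param noise_sd Per-coordinate Gaussian noise SD (mm).
#' @param seed Integer seed.
#' @param n_centers Number of RBF centers of each random field.
#' @return List with `clouds` (list of [point_cloud()]), `landmarks`
#'   (list of [landmark_set()]), `true_mean` (the template).
#' @export
gen_body_clouds <- function(template, template_lm, n_subjects = 4L,
                            deform_amp = 10, rot_amp = 20, noise_sd = 1,
                            seed = 1L, n_centers = 8L) {
  stopifnot(inherits(template, "point_cloud"), n_subjects >= 2L)
  P <- template$points
  L <- template_lm$coords
  .with_seed(seed, {
    bb_lo <- apply(P, 2L, min); bb_hi <- apply(P, 2L, max)
    span <- max(bb_hi - bb_lo)
    centers <- sapply(seq_len(3L), function(j)
      stats::runif(n_centers, bb_lo[j], bb_hi[j]))
    widths <- stats::runif(n_centers, 0.3, 0.6) * span
    # per-subject RBF coefficients, constrained zero-mean across subjects
    A <- array(stats::rnorm(n_subjects * n_centers * 3L), c(n_subjects, n_centers, 3L))
    A <- sweep(A, c(2L, 3L), apply(A, c(2L, 3L), mean))
    field_at <- function(X, a) {
      K <- exp(-(.pairwise_dist(X, centers) / rep(widths, each = nrow(X)))^2)
      K %*% a
    }
    # scale so the largest subject displacement is about deform_amp
    peak <- max(vapply(seq_len(n_subjects), function(g)
      max(abs(field_at(P, A[g, , ]))), numeric(1)))
    scale <- if (peak > 0 && deform_amp > 0) deform_amp / peak else 0
    clouds <- vector("list", n_subjects)
    lms <- vector("list", n_subjects)
    for (g in seq_len(n_subjects)) {
      a <- A[g, , ] * scale
      Pg <- P + field_at(P, a)
      Lg <- L + field_at(L, a)
      axis <- stats::rnorm(3L); axis <- axis / sqrt(sum(axis^2))
      Rg <- .rotation_matrix(axis, stats::runif(1L, 0, rot_amp))
      Pg <- Pg %*% Rg
      Lg <- Lg %*% Rg
      if (noise_sd > 0)
        Pg <- Pg + matrix(stats::rnorm(length(Pg), 0, noise_sd), nrow(Pg))
      clouds[[g]] <- point_cloud(Pg, template$faces)
      lms[[g]] <- landmark_set(template_lm$names, Lg)
    }
    list(clouds = clouds, landmarks = lms, true_mean = template)
  })
}

#' Generate a synthetic foam load-unload test
#'
#' Samples the loading branch from [loading_stress()] and the
#' unloading branch from [unloading_stress()] at the given parameters,
#' with additive zero-truncated Gaussian noise.
#'
#' @param params A [foam_params()].
#' @param eps_max Reversal strain (within the load-curve domain).
#' @param n_points Samples per branch.
#' @param noise_sd Noise SD (MPa).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return A [uniaxial_test()].
#' @export
gen_foam_test <- function(params, eps_max, n_points = 50L, noise_sd = 0,
                          seed = NULL) {
  stopifnot(inherits(params, "foam_params"))
  if (noise_sd > 0 && is.null(seed)) stop("gen_foam_test: noise needs a seed")
  e_load <- seq(0, eps_max, length.out = n_points)
  e_unload <- seq(eps_max, 0, length.out = n_points)[-1L]
  s_load <- loading_stress(e_load, params$load_curve)
  s_unload <- unloading_stress(e_unload, eps_max, params$load_curve,
                               params$hu, params$shape)
  strain <- c(e_load, e_unload)
  stress <- c(s_load, s_unload)
  if (noise_sd > 0)
    stress <- .with_seed(seed,
      pmax(stress + stats::rnorm(length(stress), 0, noise_sd), 0))
  uniaxial_test(strain, stress, noise_sd = noise_sd)
}

#' Default internal-response effect models for condition series
#'
#' Smooth angle-response curves for the internal metrics of a seat
#' adjustment sweep: a monotone decreasing vertebral stress, a U-shaped
#' disc stress with its minimum inside the sweep, and a monotone
#' increasing disc strain. Values are in the low-MPa / percent-strain
#' range typical of seated lumbar loading.
#'
#' @param kind `"whole_chair_flip"` or `"backrest_flip"`.
#' @return Named list of functions of the angle (degrees).
#' @export
default_effect_model <- function(kind = c("whole_chair_flip", "backrest_flip")) {
  kind <- match.arg(kind)
  if (kind == "whole_chair_flip") {
    list(vertebral_max_stress = function(a) 2.4 - 0.02 * a,
         disc_max_stress = function(a) 0.55 + 0.0006 * (a - 15)^2,
         disc_max_strain = function(a) 0.08 + 0.002 * a)
  } else {
    list(vertebral_max_stress = function(a) 1.8 + 0.025 * a,
         disc_max_stress = function(a) 0.50 + 0.012 * a,
         disc_max_strain = function(a) 0.07 + 0.0025 * a)
  }
}

#' Generate a synthetic multi-angle condition series
#'
#' Produces, for each adjustment angle, a cushion and a backrest
#' pressure map whose peaks migrate with the angle (load moves from the
#' cushion onto the backrest as the seat or backrest reclines) and an
#' internal-response row from the effect model plus Gaussian noise.
#'
#' @param kind `"whole_chair_flip"` or `"backrest_flip"`.
#' @param angles Adjustment angles (degrees), >= 3 of them.
#' @param effect_model Named list of functions of angle for
#'   `vertebral_max_stress`, `disc_max_stress`, `disc_max_strain`;
#'   default [default_effect_model()].
#' @param internal_noise_sd Relative noise SD on internal responses.
#' @param noise_sd Pressure noise SD (kPa).
#' @param seed Integer seed.
#' @return An object of class `condition_series`: list with `kind`,
#'   `angles`, and `conditions`, each condition holding `angle`,
#'   `cushion`, `backrest` ([pressure_map()]s) and `internal`.
#' @export
gen_condition_series <- function(kind = c("whole_chair_flip", "backrest_flip"),
                                 angles, effect_model = NULL,
                                 internal_noise_sd = 0.02, noise_sd = 0.3,
                                 seed = 1L) {
  kind <- match.arg(kind)
  if (length(angles) < 3L) stop("gen_condition_series: need >= 3 angles")
  if (is.null(effect_model)) effect_model <- default_effect_model(kind)
  conds <- .with_seed(seed, lapply(seq_along(angles), function(i) {
    a <- angles[i]
    sub_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    f <- a / max(abs(angles) + 1e-9)            # 0..1 recline fraction
    # reclining shifts load from the cushion onto the backrest: cushion
    # peaks fade and its patch shrinks while the backrest patch grows
    if (kind == "whole_chair_flip") {
      cu <- cushion_scenario(seed = sub_seed, peak_kpa = 8 - 3.5 * f,
                             noise_sd = noise_sd,
                             ellipse_semi = c(17 - 5 * f, 11 - 3 * f))
      ba <- backrest_scenario(seed = sub_seed + 1L, peak_kpa = 5 + 3 * f,
                              noise_sd = noise_sd,
                              ellipse_semi = c(13 + 4 * f, 8 + 2.5 * f))
    } else {
      cu <- cushion_scenario(seed = sub_seed, peak_kpa = 8 - 1.5 * f,
                             noise_sd = noise_sd,
                             ellipse_semi = c(17 - 2 * f, 11 - f))
      ba <- backrest_scenario(seed = sub_seed + 1L, peak_kpa = 5 + 4 * f,
                              noise_sd = noise_sd,
                              ellipse_semi = c(13 + 4 * f, 8 + 2.5 * f))
    }
    internal <- lapply(effect_model, function(fun) {
      v <- fun(a)
      v * (1 + stats::rnorm(1L, 0, internal_noise_sd))
    })
    list(angle = a, cushion = gen_pressure_map(cu),
         backrest = gen_pressure_map(ba), internal = internal)
  }))
  structure(list(kind = kind, angles = as.numeric(angles), conditions = conds),
            class = "condition_series")
}
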