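# Surface-comfort statistics on body pressure maps: contact cells, the
# SPD uniformity statistic, max/average pressure and contact area,
# fixed-width pressure binning, the waist/back and hip/legs row
# partitions, and ideal-range comfort classification.

.region_values <- function(map, region) {
  stopifnot(inherits(map, "pressure_map"), inherits(region, "region_mask"))
  cells <- region$cells
  if (nrow(cells) && (max(cells[, 1L]) > nrow(map$grid) ||
                      max(cells[, 2L]) > ncol(map$grid)))
    stop("region '", region$name, "' has cells outside the grid")
  map$grid[cells]
}

#' Contact cells of a region
#'
#' Cells of a region whose pressure strictly exceeds the contact
#' threshold. The default threshold 0 implements the "non-zero units"
#' reading of contact; a positive threshold models a sensor noise
#' floor.
#'
#' @param map A [pressure_map()].
#' @param region A [region_mask()]; defaults to the whole map.
#' @param threshold Contact threshold in kPa (strictly exclusive).
#' @return Integer matrix of (row, col) indices of contact cells
#'   (possibly 0 rows).
#' @export
contact_cells <- function(map, region = whole_region(map), threshold = 0) {
  vals <- .region_values(map, region)
  region$cells[vals > threshold, , drop = FALSE]
}

#' Seat pressure distribution (SPD) uniformity
#'
#' Computes the SPD statistic over the contact cells of a region:
#' \deqn{SPD = \sum_i (p_i - p_{ave})^2 / (4 n p_{ave}^2)}
#' where the sum runs over the n contact cells and \eqn{p_{ave}} is
#' their mean pressure. SPD is dimensionless and >= 0; lower values
#' mean a more uniform (more comfortable) distribution, and 1 - SPD is
#' conventionally plotted so that higher is better.
#'
#' @inheritParams contact_cells
#' @return SPD value (dimensionless, >= 0).
#' @examples
#' pm <- pressure_map(matrix(c(1, 3), 1), c(10, 10), "cushion")
#' compute_spd(pm)  # 0.0625
#' @export
compute_spd <- function(map, region = whole_region(map), threshold = 0) {
  vals <- .region_values(map, region)
  p <- vals[vals > threshold]
  if (!length(p))
    stop("compute_spd: no contact cells in region '", region$name,
         "' (SPD is undefined without contact)")
  p_ave <- mean(p)
  sum((p - p_ave)^2) / (4 * length(p) * p_ave^2)
}

#' All surface pressure metrics for one region
#'
#' Maximum pressure, average pressure (over contact cells only),
#' contact area, contact-cell count, SPD, and 1 - SPD.
#'
#' @inheritParams contact_cells
#' @return An object of class `pressure_metrics`: a list with fields
#'   `p_max` (kPa), `p_ave` (kPa), `contact_area` (cm^2), `n_contact`,
#'   `spd`, `one_minus_spd`.
#' @export
compute_metrics <- function(map, region = whole_region(map), threshold = 0) {
  vals <- .region_values(map, region)
  p <- vals[vals > threshold]
  if (!length(p))
    stop("compute_metrics: no contact cells in region '", region$name,
         "' (p_max, p_ave and SPD are undefined without contact)")
  cell_area_cm2 <- prod(map$cell_pitch) / 100   # mm^2 -> cm^2
  p_ave <- mean(p)
  spd <- sum((p - p_ave)^2) / (4 * length(p) * p_ave^2)
  structure(list(
    p_max = max(p),
    p_ave = p_ave,
    contact_area = length(p) * cell_area_cm2,
    n_contact = length(p),
    spd = spd,
    one_minus_spd = 1 - spd
  ), class = "pressure_metrics")
}

#' @export
print.pressure_metrics <- function(x, ...) {
  cat(sprintf(paste0("pressure_metrics: p_max %.3g kPa, p_ave %.3g kPa, ",
                     "area %.3g cm^2 (n = %d), SPD %.4g\n"),
              x$p_max, x$p_ave, x$contact_area, x$n_contact, x$spd))
  invisible(x)
}

#' Fixed-width pressure histogram of contact cells
#'
#' Counts contact cells into half-open pressure bins
#' \eqn{[k w, (k+1) w)} starting at 0 — the standard comparison of
#' simulated and measured maps bins at w = 4 kPa. Counts sum to the
#' number of contact cells.
#'
#' @inheritParams contact_cells
#' @param bin_width Bin width in kPa (> 0), default 4.
#' @return Named integer vector of counts; names give the bin
#'   intervals.
#' @export
bin_histogram <- function(map, region = whole_region(map), bin_width = 4,
                          threshold = 0) {
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_histogram: bin_width must be > 0")
  vals <- .region_values(map, region)
  p <- vals[vals > threshold]
  if (!length(p)) {
    counts <- integer(1L)
    names(counts) <- sprintf("[0,%g)", bin_width)
    return(counts)
  }
  idx <- floor(p / bin_width)        # half-open [k*w, (k+1)*w)
  nb <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nb)
  names(counts) <- sprintf("[%g,%g)", bin_width * (seq_len(nb) - 1L),
                           bin_width * seq_len(nb))
  counts
}

.partition_rows <- function(map, split_row, upper_name, lower_name) {
  nr <- nrow(map$grid)
  if (!is.finite(split_row) || split_row < 1L || split_row > nr)
    stop("partition: split row ", split_row, " outside 1..", nr)
  split_row <- as.integer(split_row)
  cols <- seq_len(ncol(map$grid))
  upper_rows <- seq_len(split_row)
  lower_rows <- if (split_row < nr) (split_row + 1L):nr else integer(0)
  mk <- function(rows, nm) {
    if (!length(rows)) {
      warning("partition: region '", nm, "' is empty at split row ", split_row)
      return(region_mask(nm, NULL, map))
    }
    region_mask(nm, as.matrix(expand.grid(row = rows, col = cols)), map)
  }
  out <- list(mk(upper_rows, upper_name), mk(lower_rows, lower_name))
  names(out) <- c(upper_name, lower_name)
  out
}

#' Partition a backrest map into waist and back regions
#'
#' The waist and back are separated at the row where the upper end of
#' the L1 vertebral body projects onto the backrest: rows below the
#' division line (toward the seat cushion; larger row indices under the
#' row-1-at-top convention) form the waist, rows at or above it the
#' back. Alternatively the division can be given as a physical height
#' from the top of the mat, converted through the row pitch.
#'
#' @param map A backrest [pressure_map()].
#' @param l1_row Row index of the L1 projection (1-based, counted from
#'   the top row).
#' @param l1_height_mm Alternative to `l1_row`: distance of the
#'   division line from the top edge of the mat in mm.
#' @return Named list of two [region_mask()]s: `waist`, `back`.
#' @export
partition_backrest <- function(map, l1_row = NULL, l1_height_mm = NULL) {
  stopifnot(inherits(map, "pressure_map"))
  if (map$interface != "backrest")
    stop("partition_backrest: map interface is '", map$interface, "'")
  if (is.null(l1_row)) {
    if (is.null(l1_height_mm))
      stop("partition_backrest: give l1_row or l1_height_mm")
    l1_row <- max(1L, min(nrow(map$grid),
                          as.integer(ceiling(l1_height_mm / map$cell_pitch[1L]))))
  }
  p <- .partition_rows(map, l1_row, upper_name = "back", lower_name = "waist")
  p[c("waist", "back")]
}

#' Partition a cushion map into hip and legs regions
#'
#' Splits a cushion map at a user-chosen row: rows at or above the
#' split (toward the backrest; smaller row indices under the
#' row-1-at-top convention) form the hip region, rows below it the
#' legs. No anatomical default is claimed; the split row depends on mat
#' placement and subject anthropometry.
#'
#' @param map A cushion [pressure_map()].
#' @param split_row Last row (1-based from the top) belonging to the
#'   hip region.
#' @param split_height_mm Alternative: distance of the division line
#'   from the top edge of the mat in mm.
#' @return Named list of two [region_mask()]s: `hip`, `legs`.
#' @export
partition_cushion <- function(map, split_row = NULL, split_height_mm = NULL) {
  stopifnot(inherits(map, "pressure_map"))
  if (map$interface != "cushion")
    stop("partition_cushion: map interface is '", map$interface, "'")
  if (is.null(split_row)) {
    if (is.null(split_height_mm))
      stop("partition_cushion: give split_row or split_height_mm")
    split_row <- max(1L, min(nrow(map$grid),
                             as.integer(ceiling(split_height_mm / map$cell_pitch[1L]))))
  }
  .partition_rows(map, split_row, upper_name = "hip", lower_name = "legs")
}

#' Default ideal maximum-pressure ranges (kPa)
#'
#' Closed ideal intervals for the regional maximum pressure under
#' static sitting: 7-11 kPa for the buttocks (hip) and 4-8 kPa for the
#' lower back (waist).
#'
#' @return Named list of length-2 numeric ranges.
#' @export
ideal_pressure_ranges <- function() {
  list(hip = c(7, 11), waist = c(4, 8))
}

#' Classify regional maximum pressure against its ideal range
#'
#' Compares `p_max` of a region's metrics with the closed ideal
#' interval configured for that region.
#'
#' @param metrics A `pressure_metrics` object (or a number taken as
#'   p_max in kPa).
#' @param region Region name with a configured range (`"hip"` or
#'   `"waist"` by default).
#' @param ranges Named list of closed intervals, default
#'   [ideal_pressure_ranges()].
#' @return One of `"below_ideal"`, `"within_ideal"`, `"above_ideal"`.
#' @examples
#' classify_comfort(9, "hip")      # within_ideal
#' classify_comfort(8.55, "waist") # above_ideal
#' @export
classify_comfort <- function(metrics, region, ranges = ideal_pressure_ranges()) {
  p_max <- if (inherits(metrics, "pressure_metrics")) metrics$p_max
           else as.numeric(metrics)
  if (!region %in% names(ranges))
    stop("classify_comfort: no ideal range configured for region '", region, "'")
  r <- ranges[[region]]
  if (length(r) != 2L || r[1L] > r[2L])
    stop("classify_comfort: malformed range for '", region, "'")
  if (p_max < r[1L]) "below_ideal"
  else if (p_max > r[2L]) "above_ideal"
  else "within_ideal"
}
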