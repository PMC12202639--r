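# Per-condition analysis orchestration and the comparison machinery:
# simulation-versus-experiment percent deviation and binned-count
# comparison, surface-versus-internal trend correspondence, and the
# end-to-end report pipeline.

#' Percent deviation of a simulated value from an experimental one
#'
#' `100 * |sim - exp| / |exp|`; the experimental value is the
#' denominator. Scale-invariant: `pd(c*sim, c*exp) = pd(sim, exp)`.
#'
#' @param sim Simulated value(s).
#' @param exp Experimental reference value(s), non-zero.
#' @return Percent deviation (>= 0), vectorized.
#' @export
percent_deviation <- function(sim, exp) {
  if (any(exp == 0)) stop("percent_deviation: undefined for exp = 0")
  100 * abs(sim - exp) / abs(exp)
}

#' Compare two binned pressure histograms
#'
#' Per-bin absolute count differences and the total-variation distance
#' `0.5 * sum |p_sim - p_exp|` of the normalized counts. Both
#' histograms must use the same binning (equal bin count; equal names
#' when both are named).
#'
#' @param sim_counts,exp_counts Count vectors from [bin_histogram()]
#'   with identical binning.
#' @return List with `per_bin_diff` (absolute count differences) and
#'   `tv_distance` (in `[0, 1]`).
#' @export
compare_histograms <- function(sim_counts, exp_counts) {
  if (length(sim_counts) != length(exp_counts))
    stop("compare_histograms: mismatched binning (", length(sim_counts),
         " vs ", length(exp_counts), " bins)")
  if (!is.null(names(sim_counts)) && !is.null(names(exp_counts)) &&
      !identical(names(sim_counts), names(exp_counts)))
    stop("compare_histograms: bin labels differ")
  if (sum(sim_counts) == 0 || sum(exp_counts) == 0)
    stop("compare_histograms: empty histogram")
  p_sim <- sim_counts / sum(sim_counts)
  p_exp <- exp_counts / sum(exp_counts)
  list(per_bin_diff = abs(sim_counts - exp_counts),
       tv_distance = 0.5 * sum(abs(p_sim - p_exp)))
}

#' Trend similarity of two condition series
#'
#' Rank correlation (Spearman by default, ties mid-ranked) between two
#' metric series recorded across the same conditions. Rank correlation
#' is invariant under any strictly increasing transform of either
#' series, which is the right notion for "the trends are similar"
#' arguments; a linear (Pearson) option is exposed.
#'
#' @param a,b Numeric series over the same >= 3 conditions.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Correlation in `[-1, 1]`.
#' @export
trend_similarity <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("trend_similarity: series lengths differ")
  if (length(a) < 3L) stop("trend_similarity: need >= 3 conditions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("trend_similarity: undefined for a constant series")
  stats::cor(a, b, method = method)
}

.metrics_report <- function(m) {
  list(p_max_kpa = m$p_max, p_ave_kpa = m$p_ave,
       contact_area_cm2 = m$contact_area, n_contact = m$n_contact,
       spd = m$spd, one_minus_spd = m$one_minus_spd)
}

#' Analyze one seat-adjustment condition
#'
#' Computes per-region pressure metrics (hip/legs from the cushion map,
#' waist/back from the backrest map), comfort classifications for the
#' regions with configured ideal ranges, and optionally spinal angles,
#' for a single condition. Deterministic: identical inputs give an
#' identical result.
#'
#' @param condition_kind `"whole_chair_flip"` or `"backrest_flip"`.
#' @param angle Adjustment angle (degrees).
#' @param cushion Optional cushion [pressure_map()].
#' @param backrest Optional backrest [pressure_map()] (at least one map
#'   is required).
#' @param cushion_split_row,l1_row Partition rows for
#'   [partition_cushion()] and [partition_backrest()].
#' @param spine Optional [spine_landmarks()].
#' @param internal Optional named list of internal responses
#'   (`vertebral_max_stress`, `disc_max_stress`, `disc_max_strain`).
#' @param threshold Contact threshold (kPa).
#' @param ranges Ideal ranges for [classify_comfort()].
#' @param spine_levels Levels for [compute_spinal_angles()].
#' @return A [condition_result()].
#' @export
analyze_condition <- function(condition_kind, angle, cushion = NULL,
                              backrest = NULL, cushion_split_row = NULL,
                              l1_row = NULL, spine = NULL, internal = NULL,
                              threshold = 0, ranges = ideal_pressure_ranges(),
                              spine_levels = spine_levels_default()) {
  if (is.null(cushion) && is.null(backrest))
    stop("analyze_condition: at least one pressure map is required (angle ",
         angle, ")")
  region_metrics <- list()
  wrap <- function(expr, what)
    tryCatch(expr, error = function(e)
      stop("analyze_condition [", condition_kind, " ", angle, " deg, ", what,
           "]: ", conditionMessage(e), call. = FALSE))
  if (!is.null(cushion)) {
    parts <- if (is.null(cushion_split_row)) list(whole = whole_region(cushion))
             else wrap(partition_cushion(cushion, cushion_split_row), "cushion")
    for (nm in names(parts))
      region_metrics[[nm]] <- wrap(compute_metrics(cushion, parts[[nm]],
                                                   threshold), nm)
  }
  if (!is.null(backrest)) {
    parts <- if (is.null(l1_row)) list(whole_backrest = whole_region(backrest))
             else wrap(partition_backrest(backrest, l1_row), "backrest")
    for (nm in names(parts))
      region_metrics[[nm]] <- wrap(compute_metrics(backrest, parts[[nm]],
                                                   threshold), nm)
  }
  comfort <- list()
  for (nm in intersect(names(region_metrics), names(ranges)))
    comfort[[nm]] <- classify_comfort(region_metrics[[nm]], nm, ranges)
  angles <- if (!is.null(spine))
    wrap(compute_spinal_angles(spine, spine_levels), "spine") else NULL
  condition_result(condition_kind, angle, region_metrics,
                   internal = internal, spine = angles,
                   comfort = if (length(comfort)) comfort else NULL)
}

.surface_metric_names <- c("p_max_kpa", "p_ave_kpa", "contact_area_cm2",
                           "one_minus_spd")

#' Cross-condition trend table
#'
#' Builds the surface-metric series (maximum pressure, average
#' pressure, contact area, 1 - SPD) of the interface relevant to the
#' condition kind (cushion for whole-chair flips, backrest for
#' backrest flips; whole-map metrics) and correlates each with each
#' internal-response series when internal data are present, or with
#' the other surface metrics otherwise.
#'
#' @param results List of [condition_result()]s for one sweep.
#' @param surface_region Region whose metrics form the surface series;
#'   default `"whole"` for cushion sweeps, `"whole_backrest"` for
#'   backrest sweeps, falling back to the first region present.
#' @param method Correlation method for [trend_similarity()].
#' @return List with `surface` (metric series matrix), `internal`
#'   (response series matrix or NULL), and `similarity` (trend
#'   correlation matrix).
#' @export
trend_table <- function(results, surface_region = NULL,
                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(results) < 3L) stop("trend_table: need >= 3 conditions")
  kind <- results[[1L]]$condition_kind
  if (is.null(surface_region)) {
    prefer <- if (kind == "whole_chair_flip") c("whole", "hip")
              else c("whole_backrest", "waist")
    have <- names(results[[1L]]$region_metrics)
    surface_region <- c(intersect(prefer, have), have)[1L]
  }
  surface <- sapply(results, function(r) {
    m <- r$region_metrics[[surface_region]]
    if (is.null(m)) stop("trend_table: region '", surface_region,
                         "' missing at angle ", r$angle)
    c(p_max_kpa = m$p_max, p_ave_kpa = m$p_ave,
      contact_area_cm2 = m$contact_area, one_minus_spd = m$one_minus_spd)
  })
  internal_names <- unique(unlist(lapply(results, function(r) names(r$internal))))
  internal <- if (length(internal_names)) {
    sapply(results, function(r) {
      vapply(internal_names, function(nm) {
        v <- r$internal[[nm]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }, numeric(1))
    })
  } else NULL
  if (is.null(dim(internal)) && !is.null(internal))
    internal <- matrix(internal, nrow = 1L, dimnames = list(internal_names))
  cols <- if (is.null(internal)) surface else internal
  sim <- matrix(NA_real_, nrow(surface), nrow(cols),
                dimnames = list(rownames(surface), rownames(cols)))
  for (i in seq_len(nrow(surface)))
    for (j in seq_len(nrow(cols)))
      sim[i, j] <- trend_similarity(surface[i, ], cols[j, ], method = method)
  list(surface_region = surface_region, surface = surface,
       internal = internal, similarity = sim)
}

#' Validate a pipeline report against the expected schema
#'
#' Checks the structural contract of a [run_pipeline()] report:
#' required top-level fields, one entry per condition with kind, angle
#' and region metric blocks (each with the six metric fields), and a
#' complete trend-similarity table.
#'
#' @param report A report list (or a path to a report JSON).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- read_report(report)
  need <- c("kind", "angles", "parameters", "conditions", "trends")
  miss <- setdiff(need, names(report))
  if (length(miss))
    stop("validate_report: missing field(s): ", paste(miss, collapse = ", "))
  if (length(report$conditions) != length(report$angles))
    stop("validate_report: ", length(report$conditions), " conditions for ",
         length(report$angles), " angles")
  metric_fields <- c("p_max_kpa", "p_ave_kpa", "contact_area_cm2",
                     "n_contact", "spd", "one_minus_spd")
  for (i in seq_along(report$conditions)) {
    cd <- report$conditions[[i]]
    for (f in c("condition_kind", "angle", "regions"))
      if (is.null(cd[[f]]))
        stop("validate_report: condition ", i, " lacks '", f, "'")
    for (rn in names(cd$regions)) {
      mf <- setdiff(metric_fields, names(cd$regions[[rn]]))
      if (length(mf))
        stop("validate_report: condition ", i, " region '", rn,
             "' lacks ", paste(mf, collapse = ", "))
    }
  }
  if (is.null(report$trends$similarity))
    stop("validate_report: missing trend similarity table")
  invisible(TRUE)
}

#' Run the full per-condition analysis pipeline
#'
#' Drives [analyze_condition()] over a sweep of seat-adjustment
#' conditions and assembles the cross-condition trend table, plus a
#' simulation-versus-experiment comparison table when experimental
#' reference values are supplied. Conditions come either from a
#' synthetic series specification (`synth` block) or from pressure-map
#' CSV files listed per condition. The configuration can be a list or
#' a YAML file path.
#'
#' Config fields: `kind`; either `synth` (`angles`, `seed`, optional
#' `internal_noise_sd`, `noise_sd`) or `conditions` (list of `angle`,
#' `cushion_csv`, `backrest_csv`, optional `internal`); optional
#' `cell_pitch`, `threshold`, `cushion_split_row`, `l1_row`,
#' `ideal_ranges`, `trend_method`, `experimental` (named reference
#' values compared by [percent_deviation()] against the matching
#' whole-map metric of the first condition).
#'
#' @param config List or YAML path.
#' @param out_dir Optional output directory; writes `report.json` and
#'   `metrics.csv` (and `trends.csv`). Reruns on identical inputs are
#'   byte-identical.
#' @return The report list, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  kind <- match.arg(config$kind, c("whole_chair_flip", "backrest_flip"))
  threshold <- config$threshold %||% 0
  ranges <- config$ideal_ranges %||% ideal_pressure_ranges()
  ranges <- lapply(ranges, as.numeric)
  split_row <- config$cushion_split_row %||% 24L
  l1_row <- config$l1_row %||% 24L
  method <- config$trend_method %||% "spearman"

  if (!is.null(config$synth)) {
    sy <- config$synth
    series <- gen_condition_series(
      kind, angles = as.numeric(sy$angles),
      internal_noise_sd = sy$internal_noise_sd %||% 0.02,
      noise_sd = sy$noise_sd %||% 0.3, seed = sy$seed %||% 1L)
    conds <- series$conditions
  } else if (!is.null(config$conditions)) {
    pitch <- as.numeric(config$cell_pitch %||% c(12.7, 12.7))
    conds <- lapply(config$conditions, function(cc) {
      read1 <- function(path, iface) {
        if (is.null(path)) return(NULL)
        if (!file.exists(path))
          stop("run_pipeline: missing file '", path, "' for condition at angle ",
               cc$angle)
        read_pressure_map(path, pitch, iface)
      }
      list(angle = as.numeric(cc$angle),
           cushion = read1(cc$cushion_csv, "cushion"),
           backrest = read1(cc$backrest_csv, "backrest"),
           internal = cc$internal)
    })
  } else stop("run_pipeline: config needs a 'synth' or 'conditions' block")

  results <- lapply(conds, function(cd)
    analyze_condition(kind, cd$angle, cushion = cd$cushion,
                      backrest = cd$backrest,
                      cushion_split_row = split_row, l1_row = l1_row,
                      internal = cd$internal, threshold = threshold,
                      ranges = ranges))
  trends <- trend_table(results, method = method)

  comparison <- NULL
  if (!is.null(config$experimental)) {
    first <- results[[1L]]
    comparison <- lapply(names(config$experimental), function(nm) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]   # "region.metric"
      simv <- first$region_metrics[[parts[1L]]][[parts[2L]]]
      if (is.null(simv))
        stop("run_pipeline: unknown experimental reference '", nm, "'")
      expv <- as.numeric(config$experimental[[nm]])
      list(metric = nm, simulated = simv, experimental = expv,
           percent_deviation = percent_deviation(simv, expv))
    })
  }

  report <- list(
    kind = kind,
    angles = vapply(results, `[[`, numeric(1), "angle"),
    parameters = list(threshold_kpa = threshold,
                      cushion_split_row = split_row, l1_row = l1_row,
                      ideal_ranges_kpa = ranges, trend_method = method),
    conditions = lapply(results, function(r) list(
      condition_kind = r$condition_kind, angle = r$angle,
      regions = lapply(r$region_metrics, .metrics_report),
      comfort = r$comfort, internal = r$internal,
      spine_angles = if (is.null(r$spine)) NULL
                     else list(cc = r$spine$cc, ttk = r$spine$ttk,
                               ll = r$spine$ll))),
    trends = list(surface_region = trends$surface_region,
                  surface = as.data.frame(t(trends$surface)),
                  internal = if (is.null(trends$internal)) NULL
                             else as.data.frame(t(trends$internal)),
                  similarity = as.data.frame(trends$similarity)),
    comparison = comparison
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
    rows <- do.call(rbind, lapply(report$conditions, function(cd)
      do.call(rbind, lapply(names(cd$regions), function(rn)
        data.frame(angle = cd$angle, region = rn,
                   as.data.frame(cd$regions[[rn]]))))))
    utils::write.csv(rows, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    sim <- as.data.frame(trends$similarity)
    utils::write.csv(cbind(surface_metric = rownames(trends$similarity), sim),
                     file.path(out_dir, "trends.csv"), row.names = FALSE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
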