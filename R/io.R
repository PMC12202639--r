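# Readers and writers for the plain-text formats the pipeline touches:
# pressure-map CSV grids, landmark CSV/JSON, OBJ/PLY meshes, spine CSV
# tables, and JSON reports. Every reader validates through the type
# constructors, so malformed input fails with the offending record
# named. All writers round-trip to 1e-9 relative.

#' Read a pressure map from a plain CSV grid
#'
#' Parses a rectangular numeric CSV (no header) as exported from a
#' pressure-mat session, one value per cell in kPa. The physical cell
#' pitch is not recorded in such exports and must be supplied.
#'
#' @param path CSV file path.
#' @param cell_pitch Length-2 numeric (row mm, col mm).
#' @param interface `"cushion"` or `"backrest"`.
#' @return A [pressure_map()].
#' @export
read_pressure_map <- function(path, cell_pitch,
                              interface = c("cushion", "backrest")) {
  interface <- match.arg(interface)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_pressure_map: empty file '", path, "'")
  rows <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop("read_pressure_map: ragged rows in '", path, "' (row ",
         which(ncols != ncols[1L])[1L], " has ", ncols[ncols != ncols[1L]][1L],
         " fields, expected ", ncols[1L], ")")
  vals <- suppressWarnings(vapply(rows, function(r) as.numeric(trimws(r)),
                                  numeric(ncols[1L])))
  grid <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
  if (any(is.na(grid))) {
    bad <- which(is.na(grid), arr.ind = TRUE)[1L, ]
    stop("read_pressure_map: non-numeric value at row ", bad[1L],
         ", column ", bad[2L], " of '", path, "'")
  }
  pressure_map(grid, cell_pitch, interface,
               origin_note = paste("read from", basename(path)))
}

#' Write a pressure map grid to CSV
#'
#' @param map A [pressure_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pressure_map <- function(map, path) {
  stopifnot(inherits(map, "pressure_map"))
  lines <- apply(map$grid, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a named landmark set (CSV or JSON)
#'
#' CSV must have columns `name,x,y,z`; JSON must be an object mapping
#' landmark names to `[x, y, z]` arrays. The format is chosen by file
#' extension.
#'
#' @param path File path (`.csv` or `.json`).
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!length(obj) || is.null(names(obj)))
      stop("read_landmarks: JSON in '", path, "' must map names to [x,y,z]")
    coords <- do.call(rbind, lapply(obj, as.numeric))
    return(landmark_set(names(obj), coords))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("read_landmarks: '", path, "' must have columns name,x,y,z")
  landmark_set(df$name, as.matrix(df[, c("x", "y", "z")]))
}

#' Write a landmark set to CSV or JSON
#'
#' @param lm A [landmark_set()].
#' @param path Output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  if (tolower(tools::file_ext(path)) == "json") {
    obj <- stats::setNames(lapply(seq_along(lm$names), function(i)
      unname(lm$coords[i, ])), lm$names)
    jsonlite::write_json(obj, path, digits = NA)
  } else {
    df <- data.frame(name = lm$names, x = lm$coords[, 1L],
                     y = lm$coords[, 2L], z = lm$coords[, 3L])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a point cloud or mesh (OBJ or ASCII PLY)
#'
#' Supports the vertex/face subset of Wavefront OBJ (`v` and triangular
#' `f` records) and ASCII PLY with vertex x/y/z properties and optional
#' triangular faces.
#'
#' @param path File path (`.obj` or `.ply`).
#' @return A [point_cloud()].
#' @export
read_cloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") return(.read_obj(path))
  if (ext == "ply") return(.read_ply(path))
  stop("read_cloud: unsupported extension '", ext, "' (use .obj or .ply)")
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  vs <- toks[vapply(toks, function(t) length(t) > 0 && t[1L] == "v", logical(1))]
  fs <- toks[vapply(toks, function(t) length(t) > 0 && t[1L] == "f", logical(1))]
  if (!length(vs)) stop("read_cloud: no vertices in OBJ '", path, "'")
  pts <- t(vapply(vs, function(t) as.numeric(t[2:4]), numeric(3)))
  faces <- NULL
  if (length(fs)) {
    faces <- t(vapply(fs, function(t) {
      if (length(t) != 4L)
        stop("read_cloud: only triangular OBJ faces supported ('",
             paste(t, collapse = " "), "')")
      # face tokens may be v, v/vt or v/vt/vn; the vertex index leads
      as.integer(vapply(strsplit(t[2:4], "/", fixed = TRUE), `[`, "", 1L))
    }, integer(3)))
  }
  point_cloud(pts, faces)
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1L]) != "ply")
    stop("read_cloud: '", path, "' is not a PLY file")
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) stop("read_cloud: PLY header not terminated")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (any(grepl("^format", hdr)) && !any(grepl("^format ascii", hdr)))
    stop("read_cloud: only ASCII PLY is supported")
  el <- grep("^element ", hdr, value = TRUE)
  counts <- stats::setNames(
    as.integer(vapply(strsplit(el, " +"), `[`, "", 3L)),
    vapply(strsplit(el, " +"), `[`, "", 2L))
  nv <- counts[["vertex"]]
  nf <- if ("face" %in% names(counts)) counts[["face"]] else 0L
  body <- trimws(lines[(hdr_end + 1L):length(lines)])
  body <- body[nzchar(body)]
  vtx <- t(vapply(strsplit(body[seq_len(nv)], " +"),
                  function(t) as.numeric(t[1:3]), numeric(3)))
  faces <- NULL
  if (nf > 0L) {
    faces <- t(vapply(strsplit(body[nv + seq_len(nf)], " +"), function(t) {
      t <- as.integer(t)
      if (t[1L] != 3L) stop("read_cloud: only triangular PLY faces supported")
      t[2:4] + 1L   # PLY indices are 0-based
    }, integer(3)))
  }
  point_cloud(vtx, faces)
}

#' Write a point cloud or mesh (OBJ or ASCII PLY)
#'
#' @param cloud A [point_cloud()].
#' @param path Output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  ext <- tolower(tools::file_ext(path))
  fmt <- function(m) apply(m, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = " "))
  if (ext == "obj") {
    lines <- paste("v", fmt(cloud$points))
    if (!is.null(cloud$faces) && nrow(cloud$faces))
      lines <- c(lines, paste("f", apply(cloud$faces, 1L, paste, collapse = " ")))
    writeLines(lines, path)
  } else if (ext == "ply") {
    nf <- if (is.null(cloud$faces)) 0L else nrow(cloud$faces)
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(cloud$points)),
             "property double x", "property double y", "property double z",
             if (nf > 0L) c(paste("element face", nf),
                            "property list uchar int vertex_indices"),
             "end_header")
    lines <- c(hdr, fmt(cloud$points))
    if (nf > 0L)
      lines <- c(lines, paste(3L, apply(cloud$faces - 1L, 1L, paste, collapse = " ")))
    writeLines(lines, path)
  } else stop("write_cloud: unsupported extension '", ext, "'")
  invisible(path)
}

#' Read vertebral endplate landmarks from CSV
#'
#' Expects columns `label,point_role,x,y,z` with `point_role` in
#' `sup_ant`, `sup_post`, `inf_ant`, `inf_post`; every vertebra needs
#' all four corners.
#'
#' @param path CSV file path.
#' @return A [spine_landmarks()].
#' @export
read_spine <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "point_role", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("read_spine: '", path, "' must have columns label,point_role,x,y,z")
  bad_role <- setdiff(unique(df$point_role), .spine_roles)
  if (length(bad_role))
    stop("read_spine: unknown point_role '", bad_role[1L], "'")
  labels <- unique(df$label)
  vert <- lapply(labels, function(lab) {
    sub <- df[df$label == lab, ]
    v <- list()
    for (role in .spine_roles) {
      r <- sub[sub$point_role == role, ]
      if (nrow(r) == 0L)
        stop("read_spine: vertebra '", lab, "' is missing corner '", role, "'")
      if (nrow(r) > 1L)
        stop("read_spine: vertebra '", lab, "' has duplicate corner '", role, "'")
      v[[role]] <- c(r$x, r$y, r$z)
    }
    v
  })
  names(vert) <- labels
  spine_landmarks(vert)
}

#' Write vertebral endplate landmarks to CSV
#'
#' @param spine A [spine_landmarks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spine <- function(spine, path) {
  stopifnot(inherits(spine, "spine_landmarks"))
  rows <- do.call(rbind, lapply(spine$labels, function(lab) {
    v <- spine$vertebrae[[lab]]
    do.call(rbind, lapply(.spine_roles, function(role)
      data.frame(label = lab, point_role = role, x = v[[role]][1L],
                 y = v[[role]][2L], z = v[[role]][3L])))
  }))
  utils::write.csv(format(rows, digits = 17), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write an analysis report to JSON
#'
#' Serializes a report list deterministically: stable key order as
#' supplied, full double precision, no trailing whitespace — rerunning
#' on identical inputs yields a byte-identical file.
#'
#' @param report A list (typically from [run_pipeline()] or
#'   [analyze_condition()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a JSON analysis report
#'
#' @param path JSON file path.
#' @return The report as a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
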