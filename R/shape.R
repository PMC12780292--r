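#' Anatomical labels for a biventricular mesh
#'
#' Index sets and ordered structures tying mesh vertices to cardiac anatomy:
#' the four surfaces (LV/RV endo- and epicardium), the valve rings (ordered
#' cyclic vertex lists), the LV apex vertex, per-surface short-axis rings from
#' base to apex (for circumferential arc lengths) and per-surface open
#' base-to-apex lines (for longitudinal arc lengths).
#'
#' @param surfaces Named list of integer vertex index vectors:
#'   `lv_endo`, `lv_epi`, `rv_endo`, `rv_epi`.
#' @param valves Named list of ordered cyclic index vectors:
#'   `mitral`, `tricuspid`, `aortic`.
#' @param apex Single vertex index (LV endocardial apex).
#' @param rings Named list (per surface) of lists of cyclic index vectors,
#'   ordered base to apex.
#' @param long_lines Named list (per surface) of lists of open base-to-apex
#'   index vectors.
#' @return An object of class `"biv_labels"`.
#' @export
new_labels <- function(surfaces, valves, apex, rings, long_lines) {
  lab <- structure(list(surfaces = lapply(surfaces, as.integer),
                        valves = lapply(valves, as.integer),
                        apex = as.integer(apex),
                        rings = lapply(rings, function(s) lapply(s, as.integer)),
                        long_lines = lapply(long_lines,
                                            function(s) lapply(s, as.integer))),
                   class = "biv_labels")
  validate_labels(lab)
  lab
}

validate_labels <- function(labels, n_vertices = NULL) {
  need_surf <- c("lv_endo", "lv_epi", "rv_endo", "rv_epi")
  miss <- setdiff(need_surf, names(labels$surfaces))
  if (length(miss)) stop("missing surface label(s): ", paste(miss, collapse = ", "))
  need_valve <- c("mitral", "tricuspid", "aortic")
  miss <- setdiff(need_valve, names(labels$valves))
  if (length(miss)) stop("missing valve ring(s): ", paste(miss, collapse = ", "))
  if (length(intersect(labels$surfaces$lv_endo, labels$surfaces$lv_epi))) {
    stop("lv_endo and lv_epi vertex sets must be disjoint")
  }
  for (s in names(labels$rings)) {
    for (r in labels$rings[[s]]) {
      if (anyDuplicated(r)) stop("ring on surface '", s, "' is not a simple cycle")
      if (!all(r %in% labels$surfaces[[s]])) {
        stop("ring index outside surface set '", s, "'")
      }
    }
  }
  for (s in names(labels$long_lines)) {
    for (l in labels$long_lines[[s]]) {
      if (anyDuplicated(l)) stop("line on surface '", s, "' is not a simple path")
      if (!all(l %in% labels$surfaces[[s]])) {
        stop("line index outside surface set '", s, "'")
      }
    }
  }
  if (!is.null(n_vertices)) {
    mx <- max(unlist(labels$surfaces), unlist(labels$valves), labels$apex,
              unlist(labels$rings), unlist(labels$long_lines))
    if (mx > n_vertices) stop("label index ", mx, " exceeds vertex count ",
                              n_vertices)
  }
  invisible(labels)
}

#' Biventricular shape: paired ED and ES meshes with shared labels
#'
#' The end-diastolic and end-systolic meshes must share topology (identical
#' vertex count and face list), giving point correspondence across frames;
#' a single label set applies to both.
#'
#' @param id Participant identifier.
#' @param ed,es [new_mesh()] objects at end-diastole and end-systole.
#' @param labels A [new_labels()] object.
#' @return An object of class `"biv_shape"`.
#' @export
new_shape <- function(id, ed, es, labels) {
  if (nrow(ed$vertices) != nrow(es$vertices)) {
    stop("ED and ES vertex counts differ (", nrow(ed$vertices), " vs ",
         nrow(es$vertices), ")")
  }
  if (!identical(ed$faces, es$faces)) stop("ED and ES face lists differ")
  validate_labels(labels, nrow(ed$vertices))
  structure(list(id = id, ed = ed, es = es, labels = labels),
            class = "biv_shape")
}

#' @export
print.biv_shape <- function(x, ...) {
  cat("<biv_shape> id=", x$id, ": ", nrow(x$ed$vertices),
      " vertices x 2 frames\n", sep = "")
  invisible(x)
}

frame_mesh <- function(shape, frame = c("ed", "es")) {
  shape[[match.arg(tolower(frame), c("ed", "es"))]]
}

#' LV wall volume and mass
#'
#' Wall volume is the volume between the LV epicardial and endocardial
#' surfaces; mass multiplies the end-diastolic wall volume by myocardial
#' density (default 1.05 g/mL, the standard CMR convention).
#'
#' @param shape A [new_shape()] object.
#' @param frame `"ed"` or `"es"`.
#' @return Wall volume in mL ([lv_wall_volume()]) or mass in g ([lv_mass()]).
#' @export
lv_wall_volume <- function(shape, frame = "ed") {
  mesh <- frame_mesh(shape, frame)
  epi <- surface_volume(mesh, shape$labels$surfaces$lv_epi)
  endo <- surface_volume(mesh, shape$labels$surfaces$lv_endo)
  wall <- epi - endo
  if (wall < 0) stop("non-positive LV wall volume (", round(wall, 2),
                     " mL); epicardium inside endocardium?")
  wall
}

#' @rdname lv_wall_volume
#' @param density Myocardial density, g/mL.
#' @export
lv_mass <- function(shape, density = 1.05) {
  lv_wall_volume(shape, "ed") * density
}

# ---- I/O: ASCII PLY geometry + JSON label sidecar -------------------------

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  hdr_end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines[1:hdr_end], value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines[1:hdr_end], value = TRUE)))
  v <- matrix(scan(text = lines[hdr_end + seq_len(nv)], quiet = TRUE),
              nv, 3, byrow = TRUE)
  fraw <- matrix(scan(text = lines[hdr_end + nv + seq_len(nf)], quiet = TRUE),
                 nf, 4, byrow = TRUE)
  if (any(fraw[, 1] != 3)) stop("non-triangular face in ", path)
  new_mesh(v, fraw[, 2:4, drop = FALSE] + 1L)
}

labels_to_json_list <- function(labels) {
  to0 <- function(x) as.integer(x) - 1L
  list(surfaces = lapply(labels$surfaces, to0),
       valves = lapply(labels$valves, to0),
       apex = to0(labels$apex),
       rings = lapply(labels$rings, function(s) lapply(s, to0)),
       long_lines = lapply(labels$long_lines, function(s) lapply(s, to0)))
}

labels_from_json_list <- function(x) {
  to1 <- function(v) as.integer(unlist(v)) + 1L
  for (v in c("mitral", "tricuspid", "aortic")) {
    if (is.null(x$valves[[v]])) stop("labels file missing valve ring '", v, "'")
  }
  new_labels(surfaces = lapply(x$surfaces, to1),
             valves = lapply(x$valves, to1),
             apex = to1(x$apex),
             rings = lapply(x$rings, function(s) lapply(s, to1)),
             long_lines = lapply(x$long_lines, function(s) lapply(s, to1)))
}

#' Read / write a biventricular shape
#'
#' Geometry is stored as two ASCII PLY files (`<stem>_ed.ply`,
#' `<stem>_es.ply`) and anatomy as a JSON sidecar (`<stem>_labels.json`) with
#' 0-based vertex indices. Vertex order is preserved so shapes round-trip to
#' within floating-point printing precision.
#'
#' @param shape A [new_shape()] object.
#' @param stem Path stem; the three file suffixes are appended.
#' @return `read_shape()` returns a [new_shape()] object; `write_shape()`
#'   returns the stem invisibly.
#' @export
write_shape <- function(shape, stem) {
  write_ply(shape$ed, paste0(stem, "_ed.ply"))
  write_ply(shape$es, paste0(stem, "_es.ply"))
  jsonlite::write_json(labels_to_json_list(shape$labels),
                       paste0(stem, "_labels.json"))
  invisible(stem)
}

#' @rdname write_shape
#' @param id Identifier for the shape read; defaults to the stem's basename.
#' @export
read_shape <- function(stem, id = basename(stem)) {
  ed <- read_ply(paste0(stem, "_ed.ply"))
  es <- read_ply(paste0(stem, "_es.ply"))
  if (nrow(ed$vertices) != nrow(es$vertices)) {
    stop("ED/ES vertex count mismatch reading ", stem)
  }
  labels <- labels_from_json_list(
    jsonlite::read_json(paste0(stem, "_labels.json")))
  validate_labels(labels, nrow(ed$vertices))
  new_shape(id, ed, es, labels)
}
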