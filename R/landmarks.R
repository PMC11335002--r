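#' Anatomical landmark set for one vertebra
#'
#' Landmarks drive centre-of-rotation placement, soft-tissue locator pairs,
#' lever arms and joint spacing. Points live in the same frame and units (mm)
#' as the vertebra mesh. Expected point names:
#'
#' * `endplate_cranial_{dorsal,ventral,left,right}` and
#'   `endplate_caudal_{dorsal,ventral,left,right}` — extremes of the two
#'   centrum endplates;
#' * `prezyg_{left,right}_{cranial,caudal}` and
#'   `postzyg_{left,right}_{cranial,caudal}` — extremes of the zygapophyseal
#'   facets (omitted on a damaged side);
#' * `arch_apex` — top of the neural arch (not the spine tip);
#' * optional `facet_{prezyg,postzyg}_{left,right}_{1..4}` — facet-surface
#'   corner polygons used by disarticulation detection.
#'
#' @param points numeric matrix (k x 3) with rownames as above.
#' @param centrum_length centrum length, mm (> 0).
#' @param endplate_area endplate area, mm^2 (> 0).
#' @param side_damage `"none"`, `"left"` or `"right"`; a damaged side has no
#'   usable zygapophysis.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, centrum_length, endplate_area,
                         side_damage = c("none", "left", "right")) {
  side_damage <- match.arg(side_damage)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be a k x 3 matrix")
  if (is.null(rownames(points))) stop("points must have names")
  if (!all(is.finite(points))) stop("non-finite landmark coordinates")
  if (!isTRUE(centrum_length > 0)) stop("centrum_length must be > 0")
  if (!isTRUE(endplate_area > 0)) stop("endplate_area must be > 0")
  req <- as.vector(outer(c("endplate_cranial", "endplate_caudal"),
                         c("dorsal", "ventral", "left", "right"), paste,
                         sep = "_"))
  missing <- setdiff(req, rownames(points))
  if (length(missing) > 0)
    stop("missing endplate landmarks: ", paste(missing, collapse = ", "))
  structure(list(points = points, centrum_length = centrum_length,
                 endplate_area = endplate_area, side_damage = side_damage),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d points, centrum length %.2f mm, damage: %s\n",
              nrow(x$points), x$centrum_length, x$side_damage))
  invisible(x)
}

.lm_point <- function(lm, name) {
  i <- match(name, rownames(lm$points))
  if (is.na(i)) return(NULL)
  lm$points[i, ]
}

.lm_facet <- function(lm, kind, side) {
  nm <- paste("facet", kind, side, 1:4, sep = "_")
  i <- match(nm, rownames(lm$points))
  if (anyNA(i)) return(NULL)
  lm$points[i, , drop = FALSE]
}

#' Centroid of a centrum endplate
#'
#' The endplate centroid is the mean of its four extreme landmarks.
#'
#' @param lm a [landmark_set()].
#' @param end `"cranial"` or `"caudal"`.
#' @return length-3 point.
#' @export
endplate_centroid <- function(lm, end = c("cranial", "caudal")) {
  end <- match.arg(end)
  nm <- paste("endplate", end, c("dorsal", "ventral", "left", "right"),
              sep = "_")
  colMeans(lm$points[nm, , drop = FALSE])
}

#' Transform a landmark set rigidly
#' @param lm a [landmark_set()].
#' @param offset translation (length 3), applied after any rotation.
#' @param axis,angle_deg,center optional rotation (see [rotate_points()]).
#' @return the transformed `landmark_set`.
#' @export
transform_landmarks <- function(lm, offset = c(0, 0, 0), axis = NULL,
                                angle_deg = 0, center = c(0, 0, 0)) {
  p <- lm$points
  if (!is.null(axis) && angle_deg != 0)
    p <- rotate_points(p, axis, angle_deg, center)
  lm$points <- sweep(p, 2, as.numeric(offset), "+")
  lm
}

#' Write/read a landmark sidecar file
#'
#' Plain-text format: scalar lines `#key value` followed by one `name x y z`
#' line per point.
#'
#' @param lm a [landmark_set()].
#' @param path file path.
#' @return `path` / a `landmark_set`.
#' @export
save_landmarks <- function(lm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#centrum_length %.12g", lm$centrum_length),
               sprintf("#endplate_area %.12g", lm$endplate_area),
               sprintf("#side_damage %s", lm$side_damage)), con)
  writeLines(sprintf("%s %.12g %.12g %.12g", rownames(lm$points),
                     lm$points[, 1], lm$points[, 2], lm$points[, 3]), con)
  invisible(path)
}

#' @rdname save_landmarks
#' @export
load_landmarks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  meta_l <- lines[startsWith(lines, "#")]
  pts_l <- lines[!startsWith(lines, "#")]
  meta <- strsplit(trimws(sub("^#", "", meta_l)), "\\s+")
  kv <- stats::setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  parts <- strsplit(trimws(pts_l), "\\s+")
  pts <- do.call(rbind, lapply(parts, function(x) as.numeric(x[2:4])))
  rownames(pts) <- vapply(parts, `[`, "", 1)
  landmark_set(pts, centrum_length = as.numeric(kv[["centrum_length"]]),
               endplate_area = as.numeric(kv[["endplate_area"]]),
               side_damage = kv[["side_damage"]])
}
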