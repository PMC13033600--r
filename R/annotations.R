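# Annotation containers and QuPath-dialect GeoJSON I/O.
#
# Coordinates are 0-based pixel units in the source-image frame, x rightward,
# y downward (the image-space convention QuPath itself uses, so no axis flip
# on import/export).

POLYGON_CLASSES <- c("tissue", "tumor", "necrosis", "hemorrhage")
POINT_CLASSES <- c("lymphocyte")

#' Create an annotation set
#'
#' Polygons (tissue / tumor / necrosis / hemorrhage outlines) and points
#' (individual lymphocytes) with class labels. Unknown class labels are kept
#' verbatim — expert files never lose data silently — but trigger a warning.
#'
#' @param polygons list of entries `list(class = <label>, coords = <n x 2
#'   matrix of (x, y) vertices>)`; each polygon needs >= 3 vertices.
#' @param points data frame with columns `class`, `x`, `y` (or `NULL`).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(polygons = list(), points = NULL) {
  if (is.null(points)) points <- data.frame(class = character(), x = double(), y = double())
  for (p in polygons) {
    if (is.null(p$class) || is.null(p$coords)) stop("polygon entries need $class and $coords")
    if (nrow(p$coords) < 3L) stop("polygons need at least 3 vertices")
    if (anyNA(p$coords) || any(!is.finite(p$coords)) || any(p$coords < 0))
      stop("polygon coordinates must be finite and non-negative")
  }
  if (nrow(points) > 0 && (anyNA(points$x) || anyNA(points$y) ||
                           any(points$x < 0) || any(points$y < 0)))
    stop("point coordinates must be finite and non-negative")
  labs <- c(vapply(polygons, `[[`, "", "class"), as.character(points$class))
  unknown <- setdiff(unique(labs), c(POLYGON_CLASSES, POINT_CLASSES))
  if (length(unknown))
    warning(sprintf("unknown annotation class(es) preserved verbatim: %s",
                    paste(unknown, collapse = ", ")))
  structure(list(polygons = polygons, points = points), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d polygons, %d points>\n",
              length(x$polygons), nrow(x$points)))
  invisible(x)
}

qp_feature_polygon <- function(p) {
  coords <- p$coords
  # GeoJSON rings are explicitly closed
  ring <- rbind(coords, coords[1, , drop = FALSE])
  list(
    type = "Feature",
    geometry = list(
      type = "Polygon",
      coordinates = list(lapply(seq_len(nrow(ring)),
                                function(i) c(ring[i, 1], ring[i, 2])))
    ),
    properties = list(objectType = "annotation",
                      classification = list(name = p$class))
  )
}

qp_feature_point <- function(cls, x, y) {
  list(
    type = "Feature",
    geometry = list(type = "Point", coordinates = c(x, y)),
    properties = list(objectType = "annotation",
                      classification = list(name = cls))
  )
}

#' Write an annotation set as QuPath-dialect GeoJSON
#'
#' Emits a `FeatureCollection` whose features carry the class label under
#' `properties.classification.name`. Feature order is deterministic: all
#' polygons first, then all points, each in insertion order.
#'
#' @param ann an [annotation_set].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_annotation_file <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  feats <- c(lapply(ann$polygons, qp_feature_polygon),
             if (nrow(ann$points) > 0)
               lapply(seq_len(nrow(ann$points)), function(i)
                 qp_feature_point(as.character(ann$points$class[i]),
                                  ann$points$x[i], ann$points$y[i])))
  fc <- list(type = "FeatureCollection", features = feats)
  txt <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write annotation file '%s'", path))
  invisible(path)
}

# locate the byte offset of a JSON parse failure from the parser's context
json_error_offset <- function(txt, err_msg) {
  m <- regmatches(err_msg, regexec("\n\\s*(.*)\n\\s*\\(right here\\)", err_msg))[[1]]
  if (length(m) == 2 && nzchar(m[2])) {
    pos <- regexpr(m[2], txt, fixed = TRUE)
    if (pos > 0) return(pos + nchar(m[2]) - 1L)
  }
  NA_integer_
}

#' Read a QuPath-dialect GeoJSON / JSON annotation file
#'
#' Accepts a GeoJSON `FeatureCollection` in the QuPath dialect (classification
#' name under `properties.classification.name`, or a plain `properties.name`)
#' — which is also the package's own export format. `Polygon` features (first
#' ring) and `MultiPolygon` features (one entry per part) become polygon
#' entries, `Point` features become point entries.
#'
#' @param path file path.
#' @return An [annotation_set].
#' @export
read_annotation_file <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) e)
  if (inherits(obj, "error")) {
    off <- json_error_offset(txt, conditionMessage(obj))
    stop(sprintf("malformed JSON in '%s' (parse failure at byte offset %s)",
                 path, ifelse(is.na(off), "unknown", off)))
  }
  feats <- obj$features
  if (is.null(feats)) stop("not a GeoJSON FeatureCollection (no 'features')")
  polys <- list(); pts_class <- character(); pts_x <- double(); pts_y <- double()
  ring_to_coords <- function(ring) {
    mat <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    n <- nrow(mat)
    if (n > 1 && all(mat[1, ] == mat[n, ])) mat <- mat[-n, , drop = FALSE]
    mat
  }
  for (f in feats) {
    g <- f$geometry
    cls <- f$properties$classification$name
    if (is.null(cls)) cls <- f$properties$name
    if (is.null(cls)) cls <- "unclassified"
    if (identical(g$type, "Polygon")) {
      polys[[length(polys) + 1L]] <- list(class = cls,
                                          coords = ring_to_coords(g$coordinates[[1]]))
    } else if (identical(g$type, "MultiPolygon")) {
      for (part in g$coordinates)
        polys[[length(polys) + 1L]] <- list(class = cls,
                                            coords = ring_to_coords(part[[1]]))
    } else if (identical(g$type, "Point")) {
      pts_class <- c(pts_class, cls)
      pts_x <- c(pts_x, g$coordinates[[1]])
      pts_y <- c(pts_y, g$coordinates[[2]])
    } else {
      stop(sprintf("unsupported geometry type '%s'", g$type))
    }
  }
  annotation_set(polys, data.frame(class = pts_class, x = pts_x, y = pts_y))
}

# Even-odd point-in-polygon test for a set of points (vectorized ray cast).
points_in_polygon <- function(px, py, coords) {
  n <- nrow(coords)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize annotation polygons of one class into a binary mask
#'
#' A mask pixel is foreground iff its center, mapped to parent-image
#' coordinates, lies inside any polygon of the requested class (even-odd fill
#' rule, so self-intersections alternate).
#'
#' @param ann an [annotation_set]; polygon coordinates are in parent-image
#'   pixels.
#' @param class_label class to rasterize; an absent class gives an all-zero
#'   mask.
#' @param shape integer `c(H, W)` of the output mask.
#' @param scale downsample factor of the mask relative to the parent image
#'   (>= 1); mask pixel (x, y) has parent-frame center `((x + 0.5) * scale,
#'   (y + 0.5) * scale)`.
#' @return A [binary_mask] with the given `scale`.
#' @export
rasterize_polygons <- function(ann, class_label, shape, scale = 1) {
  stopifnot(inherits(ann, "annotation_set"))
  if (scale < 1) stop("scale must be >= 1")
  if (length(shape) != 2L || any(shape < 1)) stop("shape must be positive c(H, W)")
  H <- shape[1]; W <- shape[2]
  sel <- Filter(function(p) identical(p$class, class_label), ann$polygons)
  g <- matrix(0L, H, W)
  if (length(sel)) {
    xs <- (rep(seq_len(W), each = H) - 0.5) * scale
    ys <- (rep(seq_len(H), times = W) - 0.5) * scale
    acc <- rep(FALSE, H * W)
    for (p in sel) acc <- acc | points_in_polygon(xs, ys, p$coords)
    g <- matrix(as.integer(acc), H, W)
  }
  binary_mask(g, scale = scale)
}
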