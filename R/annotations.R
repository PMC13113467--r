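#' Construct an annotation document
#'
#' An annotation document is the in-memory form of a Labelme-style polygon
#' annotation: image dimensions plus a list of labelled polygons in pixel
#' coordinates. Coordinates are 0-based with x = column and y = row, as
#' written by Labelme; the pixel at (row r, col c) covers the unit square
#' with centre (c + 0.5, r + 0.5).
#'
#' @param height,width Image dimensions in pixels.
#' @param shapes List of shapes; each shape is a list with `label` (a class
#'   name) and `points` (an n x 2 numeric matrix of (x, y) vertices, n >= 3).
#' @param image_path Optional image file name recorded in the document.
#' @return An `annotation_document` object.
#' @export
annotation_document <- function(height, width, shapes = list(),
                                image_path = "") {
  assert_that(height >= 1 && width >= 1, "image dimensions must be positive")
  shapes <- lapply(shapes, function(s) {
    assert_that(is.list(s) && !is.null(s$label) && !is.null(s$points),
                "each shape needs a label and points")
    pts <- as.matrix(s$points)
    storage.mode(pts) <- "double"
    assert_that(ncol(pts) == 2 && nrow(pts) >= 3,
                "polygon needs >= 3 (x, y) vertices")
    list(label = as.character(s$label), points = pts)
  })
  structure(list(height = as.integer(height), width = as.integer(width),
                 shapes = shapes, image_path = image_path),
            class = "annotation_document")
}

#' @export
print.annotation_document <- function(x, ...) {
  cat(sprintf("annotation_document: %dx%d, %d shape(s)\n",
              x$height, x$width, length(x$shapes)))
  for (s in x$shapes) {
    cat(sprintf("  %s: %d vertices\n", s$label, nrow(s$points)))
  }
  invisible(x)
}

#' Read a Labelme JSON annotation
#'
#' Parses the `shapes`/`label`/`points` dialect written by the Labelme
#' annotation tool and by [write_annotation()].
#'
#' @param path Path to a Labelme JSON file.
#' @param schema Optional [label_schema()]; when given, every shape label is
#'   validated against it and an unknown label raises an error listing the
#'   valid names.
#' @return An [annotation_document()].
#' @export
read_annotation <- function(path, schema = NULL) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  for (field in c("imageHeight", "imageWidth")) {
    if (is.null(doc[[field]])) {
      stop("malformed annotation ", path, ": missing field '", field, "'",
           call. = FALSE)
    }
  }
  shapes <- lapply(doc$shapes %||% list(), function(s) {
    if (is.null(s$label) || is.null(s$points)) {
      stop("malformed annotation ", path,
           ": shape missing field 'label' or 'points'", call. = FALSE)
    }
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(p[1:2])))
    list(label = s$label, points = pts)
  })
  if (!is.null(schema)) {
    for (s in shapes) schema_id(schema, s$label)
  }
  annotation_document(doc$imageHeight, doc$imageWidth, shapes,
                      doc$imagePath %||% "")
}

#' Write a Labelme JSON annotation
#'
#' @param doc An [annotation_document()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(doc, path) {
  stopifnot(inherits(doc, "annotation_document"))
  out <- list(
    version = "5.5.0",
    flags = stats::setNames(list(), character()),
    shapes = lapply(doc$shapes, function(s) {
      list(label = s$label,
           points = lapply(seq_len(nrow(s$points)),
                           function(i) as.numeric(s$points[i, ])),
           group_id = NULL,
           shape_type = "polygon",
           flags = stats::setNames(list(), character()))
    }),
    imagePath = doc$image_path,
    imageData = NULL,
    imageHeight = doc$height,
    imageWidth = doc$width
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = FALSE)
  invisible(path)
}

# Even-odd scanline fill of one polygon into an existing integer mask.
# Pixel centres sit at (col + 0.5, row + 0.5) in 0-based Labelme coordinates.
fill_polygon <- function(mask, pts, id) {
  H <- nrow(mask); W <- ncol(mask)
  x <- pts[, 1]; y <- pts[, 2]
  n <- length(x)
  x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
  r0 <- max(0L, floor(min(y) - 0.5))
  r1 <- min(H - 1L, ceiling(max(y)))
  if (r1 < r0) return(mask)
  for (r in r0:r1) {
    yc <- r + 0.5
    # half-open rule: edge crossed when min(y) <= yc < max(y)
    cross <- which((y <= yc & y2 > yc) | (y2 <= yc & y > yc))
    if (!length(cross)) next
    xs <- x[cross] + (yc - y[cross]) * (x2[cross] - x[cross]) /
      (y2[cross] - y[cross])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c0 <- max(0L, ceiling(xs[k] - 0.5))
      c1 <- min(W - 1L, ceiling(xs[k + 1] - 0.5) - 1L)
      if (c1 >= c0) mask[r + 1L, (c0 + 1L):(c1 + 1L)] <- id
    }
  }
  mask
}

# TRUE when any two non-adjacent edges of the polygon properly intersect.
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  if (n < 4) return(FALSE)
  seg <- cbind(pts, pts[c(2:n, 1), ])
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross2(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross2(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross2(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross2(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize polygon annotations into a label mask
#'
#' Converts an annotation document into an H x W integer label mask. Pixels
#' whose centre falls inside a polygon (even-odd rule) receive the polygon's
#' class id; shapes are painted in document order so later shapes overwrite
#' earlier ones; untouched pixels stay 0 (background). Out-of-bounds
#' vertices are clipped to the image with a warning; self-intersecting
#' polygons are filled even-odd with a warning.
#'
#' @param doc An [annotation_document()].
#' @param schema A [label_schema()] resolving every shape label.
#' @return An H x W integer matrix of class ids (a label mask).
#' @examples
#' sch <- label_schema()
#' doc <- annotation_document(8, 8, list(
#'   list(label = "BL", points = rbind(c(1, 1), c(5, 1), c(5, 4), c(1, 4)))
#' ))
#' m <- rasterize_annotation(doc, sch)
#' sum(m == schema_id(sch, "BL"))  # 4 x 3 = 12 pixels
#' @export
rasterize_annotation <- function(doc, schema) {
  stopifnot(inherits(doc, "annotation_document"),
            inherits(schema, "label_schema"))
  mask <- matrix(0L, doc$height, doc$width)
  for (s in doc$shapes) {
    id <- schema_id(schema, s$label)
    pts <- s$points
    if (any(pts[, 1] < 0 | pts[, 1] > doc$width |
            pts[, 2] < 0 | pts[, 2] > doc$height)) {
      warning("clipping out-of-bounds vertices for shape '", s$label, "'",
              call. = FALSE)
      pts[, 1] <- pmin(pmax(pts[, 1], 0), doc$width)
      pts[, 2] <- pmin(pmax(pts[, 2], 0), doc$height)
    }
    if (polygon_self_intersects(pts)) {
      warning("self-intersecting polygon for shape '", s$label,
              "'; applying even-odd fill", call. = FALSE)
    }
    mask <- fill_polygon(mask, pts, id)
  }
  mask
}

#' Write a label mask as a grayscale PNG
#'
#' The pixel value of the 8-bit grayscale PNG is the class id itself
#' (stored as id/255), so masks round-trip exactly through
#' [read_mask_png()].
#'
#' @param mask Integer label mask (H x W).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  assert_that(all(mask >= 0 & mask <= 255), "mask ids must be in 0..255")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a label mask written by [write_mask_png()]
#' @param path PNG path.
#' @return Integer label mask.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write a grayscale intensity image as PNG
#' @param img Numeric matrix in `[0, 1]` (H x W).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a grayscale intensity image
#'
#' Colour PNGs/JPEGs are converted to grayscale by channel averaging.
#' @param path PNG path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    nc <- min(dim(img)[3], 3)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  img
}
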