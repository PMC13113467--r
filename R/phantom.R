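# Seeded speckle-phantom generator. The phantoms emulate the statistical
# structure of fetal abdominal ultrasound planes - an elliptical abdomen,
# anechoic blobs (stomach, bladder), thin low-contrast tubes (umbilical
# vein, inferior vena cava), an echogenic spine wedge, lateralised kidneys,
# multiplicative speckle and a depth attenuation gradient - not sonographic
# physics. Every image comes with a ground-truth mask and a polygon
# annotation that re-rasterizes to that mask exactly.

ellipse_poly <- function(cx, cy, rx, ry, angle = 0, n = 48L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x0 <- rx * cos(t); y0 <- ry * sin(t)
  a <- angle * pi / 180
  cbind(cx + x0 * cos(a) - y0 * sin(a),
        cy + x0 * sin(a) + y0 * cos(a))
}

tube_poly <- function(cx, cy, half_len, half_wid, angle = 0) {
  a <- angle * pi / 180
  ux <- cos(a); uy <- sin(a)      # along the tube
  vx <- -sin(a); vy <- cos(a)     # across
  rbind(
    c(cx - half_len * ux - half_wid * vx, cy - half_len * uy - half_wid * vy),
    c(cx + half_len * ux - half_wid * vx, cy + half_len * uy - half_wid * vy),
    c(cx + half_len * ux + half_wid * vx, cy + half_len * uy + half_wid * vy),
    c(cx - half_len * ux + half_wid * vx, cy - half_len * uy + half_wid * vy)
  )
}

wedge_poly <- function(cx, cy, rx, ry) {
  rbind(c(cx, cy - ry), c(cx + rx, cy + ry), c(cx - rx, cy + ry))
}

shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Structure templates: positions/radii relative to the abdominal ellipse
# (x right, y down; posterior structures have y > 0), signed intensity
# contrast against the intra-abdominal background.
structure_templates <- function() {
  list(
    UV   = list(prim = "tube",    cx =  0.15, cy = -0.12, rx = 0.28,
                ry = 0.050, angle = -30, contrast = -0.23),
    IVC  = list(prim = "ellipse", cx =  0.14, cy =  0.42, rx = 0.09,
                ry = 0.055, angle = 0,   contrast = -0.12),
    ST   = list(prim = "ellipse", cx = -0.38, cy = -0.12, rx = 0.22,
                ry = 0.150, angle = 20,  contrast = -0.33),
    AO   = list(prim = "ellipse", cx = -0.12, cy =  0.45, rx = 0.07,
                ry = 0.070, angle = 0,   contrast = -0.27),
    SP   = list(prim = "wedge",   cx =  0.00, cy =  0.72, rx = 0.16,
                ry = 0.140, angle = 0,   contrast =  0.40),
    CORD = list(prim = "ellipse", cx =  0.05, cy = -0.55, rx = 0.16,
                ry = 0.110, angle = 0,   contrast = -0.20),
    BL   = list(prim = "ellipse", cx =  0.00, cy =  0.10, rx = 0.30,
                ry = 0.220, angle = 0,   contrast = -0.35),
    UAS  = list(prim = "ellipse", cx =  0.00, cy = -0.35, rx = 0.08,
                ry = 0.060, angle = 0,   contrast = -0.12),
    K    = list(prim = "ellipse", cx =  0.00, cy =  0.25, rx = 0.20,
                ry = 0.280, angle = 0,   contrast = -0.15),
    LK   = list(prim = "ellipse", cx = -0.42, cy =  0.30, rx = 0.17,
                ry = 0.110, angle = 25,  contrast = -0.15),
    RK   = list(prim = "ellipse", cx =  0.42, cy =  0.30, rx = 0.17,
                ry = 0.110, angle = -25, contrast = -0.15),
    IB   = list(prim = "wedge",   cx = -0.35, cy =  0.52, rx = 0.12,
                ry = 0.100, angle = 0,   contrast =  0.35),
    RIB  = list(prim = "tube",    cx = -0.65, cy = -0.05, rx = 0.22,
                ry = 0.035, angle = 75,  contrast =  0.35)
  )
}

#' Structure subset rendered for each standard plane
#'
#' @param plane One of [plane_types()].
#' @return Character vector of class names present in that plane's phantom.
#' @export
plane_structures <- function(plane) {
  assert_plane(plane)
  switch(plane,
         ACS  = c("UV", "IVC", "ST", "AO", "SP"),
         UCS  = c("UV", "CORD", "UAS", "SP"),
         BHS  = c("BL", "UAS", "SP"),
         BKHS = c("LK", "RK", "SP", "RIB"),
         LKS  = c("LK", "RIB", "SP"),
         RKS  = c("RK", "RIB", "SP"),
         BKCS = c("K", "IB", "SP"))
}

#' Phantom specification
#'
#' @param plane Standard plane to emulate.
#' @param size Image side length in pixels (square images).
#' @param speckle_cv Coefficient of variation of the multiplicative speckle
#'   field (0 disables speckle).
#' @param speckle_smooth Half-width of the box smoothing applied to the raw
#'   Rayleigh noise before standardisation (grain size, pixels).
#' @param attenuation Linear depth attenuation: intensity is scaled by
#'   `1 - attenuation * depth_fraction` (0 disables).
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @param geometry Optional explicit geometry (from [sample_geometry()]),
#'   e.g. a patient's base anatomy; when `NULL` geometry is drawn from the
#'   plane's priors using `seed`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(plane = "ACS", size = 128L, speckle_cv = 0.25,
                         speckle_smooth = 1L, attenuation = 0.15,
                         seed = 1L, geometry = NULL) {
  assert_plane(plane)
  assert_that(size >= 32, "phantom size must be >= 32 pixels")
  structure(list(plane = plane, size = as.integer(size),
                 speckle_cv = speckle_cv,
                 speckle_smooth = as.integer(speckle_smooth),
                 attenuation = attenuation, seed = as.integer(seed),
                 geometry = geometry),
            class = "phantom_spec")
}

# Keep paired kidneys on their own side of the midline so that horizontal
# flip augmentation with label swap is meaningfully testable.
enforce_laterality <- function(class, cx) {
  if (class == "LK") return(min(cx, -0.2))
  if (class == "RK") return(max(cx, 0.2))
  cx
}

#' Draw a phantom geometry from the plane priors
#'
#' Samples the abdominal ellipse and per-structure positions/sizes (bounded
#' jitter around the plane's templates). A structure whose polygon cannot be
#' placed inside the image after bounded retries raises an error naming it.
#'
#' @param plane Standard plane.
#' @param size Image side length (pixels).
#' @param seed Integer seed.
#' @return A geometry list (abdomen ellipse + per-structure polygons with
#'   contrasts and nominal areas).
#' @export
sample_geometry <- function(plane, size = 128L, seed = 1L) {
  templates <- structure_templates()
  with_seed(seed, {
    cx <- size / 2 + stats::runif(1, -0.02, 0.02) * size
    cy <- size / 2 + stats::runif(1, -0.02, 0.02) * size
    rx <- size * stats::runif(1, 0.38, 0.42)
    ry <- size * stats::runif(1, 0.32, 0.36)
    structures <- list()
    for (cls in plane_structures(plane)) {
      tpl <- templates[[cls]]
      ok <- FALSE
      for (try in 1:10) {
        pcx <- enforce_laterality(cls, tpl$cx + stats::runif(1, -0.05, 0.05))
        pcy <- tpl$cy + stats::runif(1, -0.05, 0.05)
        scale <- stats::runif(1, 0.9, 1.1)
        prx <- tpl$rx * scale
        pry <- tpl$ry * scale
        gx <- cx + pcx * rx
        gy <- cy + pcy * ry
        poly <- switch(tpl$prim,
                       ellipse = ellipse_poly(gx, gy, prx * rx, pry * ry,
                                              tpl$angle),
                       tube = tube_poly(gx, gy, prx * rx, pry * ry,
                                        tpl$angle),
                       wedge = wedge_poly(gx, gy, prx * rx, pry * ry))
        if (all(poly[, 1] >= 1 & poly[, 1] <= size - 1 &
                poly[, 2] >= 1 & poly[, 2] <= size - 1)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place structure '", cls, "' inside the image",
             call. = FALSE)
      }
      nominal <- shoelace_area(poly)
      structures[[cls]] <- list(class = cls, poly = poly,
                                contrast = tpl$contrast,
                                area_nominal = nominal,
                                area_range = c(0.45, 1.8) * nominal)
    }
    list(plane = plane, size = size,
         abdomen = list(cx = cx, cy = cy, rx = rx, ry = ry),
         structures = structures)
  })
}

#' Perturb a base geometry (same patient, new image)
#'
#' Shifts every structure by at most `pos_jitter` pixels and rescales it by
#' at most `size_jitter`, emulating repeated acquisitions of one patient's
#' anatomy.
#'
#' @param geometry A [sample_geometry()] result.
#' @param seed Integer seed.
#' @param pos_jitter Max absolute translation (pixels).
#' @param size_jitter Max relative rescaling.
#' @return Perturbed geometry.
#' @export
perturb_geometry <- function(geometry, seed, pos_jitter = 2,
                             size_jitter = 0.05) {
  with_seed(seed, {
    geometry$structures <- lapply(geometry$structures, function(s) {
      dx <- stats::runif(1, -pos_jitter, pos_jitter)
      dy <- stats::runif(1, -pos_jitter, pos_jitter)
      sc <- stats::runif(1, 1 - size_jitter, 1 + size_jitter)
      ctr <- colMeans(s$poly)
      s$poly <- sweep(sweep(s$poly, 2, ctr), 2, c(1, 1) * sc, `*`)
      s$poly <- sweep(s$poly, 2, ctr + c(dx, dy), `+`)
      s$poly[, 1] <- pmin(pmax(s$poly[, 1], 0), geometry$size)
      s$poly[, 2] <- pmin(pmax(s$poly[, 2], 0), geometry$size)
      s
    })
    geometry
  })
}

#' Multiplicative speckle field
#'
#' Rayleigh-distributed noise, box-smoothed to set the grain size, then
#' standardised to mean 1 and standard deviation `cv`; multiplying a flat
#' image by the field yields exactly the requested coefficient of variation.
#'
#' @param H,W Field dimensions.
#' @param cv Target coefficient of variation.
#' @param smooth Box smoothing half-width in pixels.
#' @param seed Integer seed.
#' @return H x W numeric matrix with mean 1.
#' @export
speckle_field <- function(H, W, cv = 0.25, smooth = 1L, seed = 1L) {
  with_seed(seed, {
    raw <- matrix(sqrt(2 * stats::rexp(H * W)), H, W)  # Rayleigh(1)
    if (smooth > 0) {
      k <- 2L * smooth + 1L
      w <- array(1 / k^2, c(1L, k, k))
      sm <- conv2d(array(raw, c(1L, H, W)), w)
      raw <- matrix(sm, H, W)
    }
    (raw - mean(raw)) / stats::sd(raw) * cv + 1
  })
}

#' Generate one phantom image
#'
#' Renders the geometry into an intensity image in `[0, 1]` (structure
#' pixels differ from the intra-abdominal background by exactly the
#' configured signed contrast before attenuation/speckle), the ground-truth
#' label mask, and a polygon annotation document that re-rasterizes to that
#' mask.
#'
#' @param spec A [phantom_spec()].
#' @param schema A [label_schema()].
#' @return List with `image` (H x W in `[0, 1]`), `mask` (H x W integer),
#'   `annotation` (an [annotation_document()]) and `geometry`.
#' @export
generate_phantom <- function(spec, schema = label_schema()) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- spec$geometry %||% sample_geometry(spec$plane, spec$size, spec$seed)
  size <- geom$size
  doc <- annotation_document(size, size, lapply(geom$structures, function(s) {
    list(label = s$class, points = s$poly)
  }))
  mask <- rasterize_annotation(doc, schema)

  bg_in <- 0.45; bg_out <- 0.05
  ab <- geom$abdomen
  abd <- fill_polygon(matrix(0L, size, size),
                      ellipse_poly(ab$cx, ab$cy, ab$rx, ab$ry, n = 72L), 1L)
  img <- matrix(bg_out, size, size)
  img[abd == 1L] <- bg_in
  for (s in geom$structures) {
    img[mask == schema_id(schema, s$class)] <- bg_in + s$contrast
  }
  if (spec$attenuation > 0) {
    depth <- (seq_len(size) - 1) / (size - 1)
    img <- img * (1 - spec$attenuation * depth)
  }
  if (spec$speckle_cv > 0) {
    img <- img * speckle_field(size, size, spec$speckle_cv,
                               spec$speckle_smooth,
                               derive_seed(spec$seed, 7L))
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, annotation = doc, geometry = geom)
}

#' Generate a synthetic dataset on disk
#'
#' Simulates `n_patients` patients; each contributes a random number of
#' images (within `images_per_patient`) of planes drawn from `planes`. All
#' images of one patient share a base anatomy per plane, perturbed by at
#' most 2 pixels / 5 percent per image, so patient-grouped splitting is
#' meaningfully testable. Writes PNG images, id-valued PNG masks, Labelme
#' JSON annotations and an index CSV.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_patients Number of synthetic patients (>= 1).
#' @param images_per_patient Integer range `c(min, max)`.
#' @param planes Plane codes to draw from.
#' @param seed Integer seed for the whole dataset.
#' @param size Image side length in pixels.
#' @param speckle_cv,attenuation Passed to [phantom_spec()].
#' @return The [dataset_index()] (invisibly), with an `anatomy` attribute
#'   logging each image's structure centroids for perturbation checks.
#' @export
generate_dataset <- function(out_dir, n_patients, images_per_patient = c(1, 3),
                             planes = "ACS", seed = 1L, size = 128L,
                             speckle_cv = 0.25, attenuation = 0.15) {
  assert_that(n_patients >= 1, "need at least one patient")
  assert_plane(planes)
  schema <- label_schema()
  for (d in c("images", "masks", "annotations")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- list(); anat <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%04d", i)
    pseed <- derive_seed(seed, i)
    n_img <- with_seed(pseed, {
      if (images_per_patient[1] == images_per_patient[2]) {
        images_per_patient[1]
      } else {
        sample(images_per_patient[1]:images_per_patient[2], 1)
      }
    })
    img_planes <- with_seed(derive_seed(pseed, 1L),
                            sample(planes, n_img, replace = TRUE))
    base_geom <- list()
    for (j in seq_len(n_img)) {
      pl <- img_planes[j]
      if (is.null(base_geom[[pl]])) {
        base_geom[[pl]] <- sample_geometry(pl, size, derive_seed(pseed, 100L +
                                                                   match(pl, plane_types())))
      }
      iseed <- derive_seed(pseed, 1000L + j)
      geom <- perturb_geometry(base_geom[[pl]], iseed)
      sp <- phantom_spec(plane = pl, size = size, speckle_cv = speckle_cv,
                         attenuation = attenuation, seed = iseed,
                         geometry = geom)
      ph <- generate_phantom(sp, schema)
      id <- sprintf("%s_%02d_%s", pid, j, pl)
      img_path <- file.path(out_dir, "images", paste0(id, ".png"))
      msk_path <- file.path(out_dir, "masks", paste0(id, ".png"))
      ann_path <- file.path(out_dir, "annotations", paste0(id, ".json"))
      write_image_png(ph$image, img_path)
      write_mask_png(ph$mask, msk_path)
      ph$annotation$image_path <- basename(img_path)
      write_annotation(ph$annotation, ann_path)
      rows[[length(rows) + 1L]] <- data.frame(
        image = img_path, annotation = ann_path, mask = msk_path,
        patient_id = pid, plane = pl, stringsAsFactors = FALSE)
      for (s in ph$geometry$structures) {
        ctr <- colMeans(s$poly)
        anat[[length(anat) + 1L]] <- data.frame(
          patient_id = pid, image = img_path, plane = pl, class = s$class,
          cx = ctr[1], cy = ctr[2], area = shoelace_area(s$poly),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  index <- dataset_index(df$image, df$annotation, df$mask, df$patient_id,
                         df$plane)
  write_dataset_index(index, file.path(out_dir, "index.csv"))
  attr(index, "anatomy") <- do.call(rbind, anat)
  invisible(index)
}
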