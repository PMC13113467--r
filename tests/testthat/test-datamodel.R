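test_that("default schema holds the 13 structures with contiguous ids", {
  sch <- label_schema()
  expect_equal(sch$n, 13L)
  expect_equal(unname(sch$classes), 0:13)
  expect_equal(names(sch$classes)[1], "background")
  expect_setequal(names(sch$classes)[-1],
                  c("UV", "IVC", "ST", "AO", "SP", "CORD", "BL", "UAS", "K",
                    "LK", "RK", "IB", "RIB"))
  expect_equal(schema_id(sch, "ST"), 3L)
  expect_equal(schema_name(sch, c(0L, 7L)), c("background", "BL"))
  expect_error(schema_id(sch, "LIVER"), "unknown label")
  expect_error(label_schema(c("A", "A")), "unique")
})

test_that("there are exactly seven standard planes", {
  expect_length(plane_types(), 7L)
  expect_setequal(plane_types(),
                  c("ACS", "UCS", "BHS", "BKHS", "LKS", "RKS", "BKCS"))
})

test_that("Labelme annotations round-trip through write/read", {
  doc <- annotation_document(32, 40, list(
    list(label = "ST", points = rbind(c(3, 4), c(20, 4), c(12, 18))),
    list(label = "SP", points = rbind(c(5, 25), c(15, 25), c(15, 30),
                                      c(5, 30)))
  ), image_path = "img.png")
  path <- withr::local_tempfile(fileext = ".json")
  write_annotation(doc, path)
  doc2 <- read_annotation(path, default_schema)
  expect_equal(doc2$height, doc$height)
  expect_equal(doc2$width, doc$width)
  expect_length(doc2$shapes, 2L)
  expect_equal(doc2$shapes[[1]]$label, "ST")
  expect_equal(doc2$shapes[[1]]$points, doc$shapes[[1]]$points)
  expect_equal(doc2$shapes[[2]]$points, doc$shapes[[2]]$points)
})

test_that("annotation reading validates structure and labels", {
  empty <- annotation_document(16, 16)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotation(empty, path)
  back <- read_annotation(path)
  expect_length(back$shapes, 0L)
  expect_equal(back$height, 16L)

  writeLines("{ not json", path)
  expect_error(read_annotation(path), "malformed JSON")

  writeLines('{"imageWidth": 8, "shapes": []}', path)
  expect_error(read_annotation(path), "imageHeight")

  tri <- annotation_document(16, 16, list(
    list(label = "XX", points = rbind(c(1, 1), c(5, 1), c(3, 5)))))
  write_annotation(tri, path)
  expect_error(read_annotation(path, default_schema), "unknown label")
})

test_that("rasterization fills rectangles with exactly w*h pixels", {
  for (dims in list(c(4, 3), c(7, 5), c(1, 9))) {
    w <- dims[1]; h <- dims[2]
    doc <- annotation_document(20, 20, list(
      list(label = "BL", points = rbind(c(2, 3), c(2 + w, 3), c(2 + w, 3 + h),
                                        c(2, 3 + h)))))
    m <- rasterize_annotation(doc, default_schema)
    expect_equal(sum(m == schema_id(default_schema, "BL")), w * h)
  }
})

test_that("rasterization agrees with a brute-force even-odd oracle", {
  set.seed(4)
  for (rep in 1:5) {
    k <- sample(3:7, 1)
    poly <- cbind(runif(k, 1, 19), runif(k, 1, 19))
    doc <- annotation_document(20, 20, list(list(label = "ST", points = poly)))
    m <- suppressWarnings(rasterize_annotation(doc, default_schema))
    oracle <- oracle_rasterize(poly, 20, 20)
    expect_equal(m == schema_id(default_schema, "ST"), oracle)
  }
})

test_that("rasterization conserves convex polygon area within a perimeter", {
  poly <- ellipse_poly <- local({
    t <- seq(0, 2 * pi, length.out = 33)[-33]
    cbind(30 + 14 * cos(t), 32 + 10 * sin(t))
  })
  doc <- annotation_document(64, 64, list(list(label = "ST", points = poly)))
  m <- rasterize_annotation(doc, default_schema)
  x <- poly[, 1]; y <- poly[, 2]; n <- nrow(poly)
  area <- abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  perim <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  expect_lt(abs(sum(m > 0) - area), perim)
})

test_that("later shapes overwrite earlier ones; empty doc gives zero mask", {
  empty <- rasterize_annotation(annotation_document(8, 8), default_schema)
  expect_true(all(empty == 0L))

  doc <- annotation_document(12, 12, list(
    list(label = "ST", points = rbind(c(1, 1), c(9, 1), c(9, 9), c(1, 9))),
    list(label = "SP", points = rbind(c(4, 4), c(11, 4), c(11, 11), c(4, 11)))
  ))
  m <- rasterize_annotation(doc, default_schema)
  # overlap region carries the later label
  expect_equal(m[6, 6], schema_id(default_schema, "SP"))
  expect_equal(m[2, 2], schema_id(default_schema, "ST"))
  expect_equal(sum(m == schema_id(default_schema, "SP")), 49)
})

test_that("out-of-bounds vertices are clipped with a warning", {
  doc <- annotation_document(10, 10, list(
    list(label = "BL", points = rbind(c(-5, 2), c(8, 2), c(8, 8), c(-5, 8)))))
  expect_warning(m <- rasterize_annotation(doc, default_schema),
                 "clipping")
  expect_equal(sum(m == schema_id(default_schema, "BL")), 8 * 6)
})

test_that("self-intersecting polygons warn and fill even-odd", {
  # bow-tie: the central crossing leaves two filled triangles
  bow <- rbind(c(1, 1), c(9, 9), c(9, 1), c(1, 9))
  doc <- annotation_document(10, 10, list(list(label = "ST", points = bow)))
  expect_warning(m <- rasterize_annotation(doc, default_schema),
                 "self-intersecting")
  oracle <- oracle_rasterize(bow, 10, 10)
  expect_equal(m == schema_id(default_schema, "ST"), oracle)
})

test_that("masks round-trip through grayscale PNG", {
  m <- matrix(sample(0:13, 30 * 20, TRUE), 30, 20)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, path)
  expect_identical(read_mask_png(path), m)
})
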