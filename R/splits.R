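#' Construct a dataset index
#'
#' A dataset index is a data frame with one row per image record: the image
#' path, its annotation (Labelme JSON) and/or mask path, an opaque patient
#' id, and the standard plane the image depicts. Several records may share a
#' patient id (one pregnant woman can contribute multiple images), which is
#' why splitting is patient-grouped.
#'
#' @param image,annotation,mask Character path columns (`annotation` and
#'   `mask` may be `NA` per record, but not both).
#' @param patient_id Non-empty character patient identifiers.
#' @param plane Plane code per record, see [plane_types()].
#' @return A `data.frame` with class `dataset_index`.
#' @export
dataset_index <- function(image, annotation = NA_character_,
                          mask = NA_character_, patient_id, plane) {
  df <- data.frame(image = as.character(image),
                   annotation = as.character(annotation),
                   mask = as.character(mask),
                   patient_id = as.character(patient_id),
                   plane = as.character(plane),
                   stringsAsFactors = FALSE)
  assert_that(all(nzchar(df$patient_id) & !is.na(df$patient_id)),
              "patient ids must be non-empty")
  assert_plane(df$plane)
  class(df) <- c("dataset_index", "data.frame")
  df
}

#' Write / read a dataset index CSV
#' @param index A [dataset_index()].
#' @param path CSV path.
#' @return `path` (write) or the index (read).
#' @export
write_dataset_index <- function(index, path) {
  utils::write.csv(as.data.frame(index), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_index
#' @export
read_dataset_index <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  dataset_index(df$image, df$annotation, df$mask, df$patient_id, df$plane)
}

# Primary plane per patient (most frequent; ties broken alphabetically) so
# that whole patients can be stratified even if their images span planes.
patient_plane_table <- function(records) {
  split_planes <- split(records$plane, records$patient_id)
  vapply(split_planes, function(p) {
    tab <- sort(table(p), decreasing = TRUE)
    names(tab)[1]
  }, character(1))
}

#' Patient-independent train/val/test split
#'
#' Shuffles patients (never individual images) with an explicit seed and
#' partitions them, stratified by plane, so that each plane's image counts
#' approximate the requested ratios. No patient id ever appears in two
#' partitions; when exact ratios and patient grouping conflict, patient
#' independence wins and the ratios are approximate.
#'
#' @param records A [dataset_index()].
#' @param ratios Numeric length-3 vector of train/val/test proportions,
#'   positive and summing to ~1.
#' @param seed Integer seed driving the patient shuffle.
#' @return `records` with an added `partition` column
#'   (`"train"|"val"|"test"`), class `split_assignment`.
#' @export
make_split <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(records, "data.frame"))
  assert_that(length(ratios) == 3 && all(ratios > 0) &&
                abs(sum(ratios) - 1) < 1e-6,
              "ratios must be three positive proportions summing to 1")
  parts <- c("train", "val", "test")
  pplane <- patient_plane_table(records)
  img_per_pat <- table(records$patient_id)
  assign <- stats::setNames(character(length(pplane)), names(pplane))

  with_seed(seed, {
    for (pl in unique(pplane)) {
      pats <- names(pplane)[pplane == pl]
      if (length(pats) < 3) {
        stop("plane ", pl, " has only ", length(pats),
             " patient(s); need >= 3 to fill train/val/test", call. = FALSE)
      }
      pats <- sample(pats)
      n_img <- sum(img_per_pat[pats])
      target <- ratios * n_img
      count <- c(0, 0, 0)
      # seed every partition with one patient (largest-ratio first), then
      # assign greedily to the largest remaining image-count deficit
      order_parts <- order(ratios, decreasing = TRUE)
      for (j in seq_along(pats)) {
        p <- pats[j]
        k <- if (j <= 3) order_parts[j] else which.max(target - count)
        assign[p] <- parts[k]
        count[k] <- count[k] + img_per_pat[[p]]
      }
    }
  })

  out <- records
  out$partition <- unname(assign[out$patient_id])
  class(out) <- c("split_assignment", class(records))
  out
}

#' Patient-independent cross-validation folds
#'
#' Assigns whole patients to `k` folds (0-based fold ids), stratified by
#' plane, with per-plane fold sizes differing by at most one patient.
#'
#' @param records A [dataset_index()].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return `records` with an added integer `fold` column in `0..k-1`,
#'   class `cv_assignment`.
#' @export
make_cv_folds <- function(records, k = 5L, seed = 1L) {
  stopifnot(inherits(records, "data.frame"))
  assert_that(k >= 2, "k must be >= 2")
  pplane <- patient_plane_table(records)
  assert_that(k <= length(pplane),
              paste0("k = ", k, " exceeds the number of patients (",
                     length(pplane), ")"))
  assign <- stats::setNames(integer(length(pplane)), names(pplane))
  with_seed(seed, {
    offset <- 0L
    for (pl in unique(pplane)) {
      pats <- sample(names(pplane)[pplane == pl])
      # continue the round-robin across planes so global fold sizes balance
      assign[pats] <- (offset + seq_along(pats) - 1L) %% k
      offset <- offset + length(pats)
    }
  })
  out <- records
  out$fold <- unname(assign[out$patient_id])
  class(out) <- c("cv_assignment", class(records))
  out
}

#' Records of one partition / fold
#'
#' @param assignment Output of [make_split()] or [make_cv_folds()].
#' @param which Partition tag (`"train"`, `"val"`, `"test"`) or fold id.
#' @return The matching subset of records.
#' @export
partition_records <- function(assignment, which) {
  if ("partition" %in% names(assignment)) {
    assignment[assignment$partition == which, , drop = FALSE]
  } else if ("fold" %in% names(assignment)) {
    assignment[assignment$fold == as.integer(which), , drop = FALSE]
  } else {
    stop("not a split or fold assignment", call. = FALSE)
  }
}
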