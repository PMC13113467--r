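#' Label schema for fetal abdominal structures
#'
#' A label schema maps class names to contiguous integer ids, with id 0
#' reserved for background. The default schema holds the 13 anatomical
#' structures segmented in standard fetal abdominal ultrasound planes:
#' umbilical vein (UV), inferior vena cava (IVC), gastric bubble (ST),
#' abdominal aorta (AO), spine (SP), umbilical cord (CORD), bladder (BL),
#' umbilical artery inlet (UAS), kidney (K), left kidney (LK), right kidney
#' (RK), ilium (IB), and ribs (RIB).
#'
#' @param classes Character vector of foreground class names, in id order
#'   (id 1, 2, ...). Must be unique and must not contain `"background"`.
#' @return An object of class `label_schema` with fields `classes` (named
#'   integer vector including `background = 0`) and `n` (number of
#'   foreground classes).
#' @examples
#' sch <- label_schema()
#' sch$n                     # 13
#' schema_id(sch, "ST")      # 3
#' @export
label_schema <- function(classes = c("UV", "IVC", "ST", "AO", "SP", "CORD",
                                     "BL", "UAS", "K", "LK", "RK", "IB",
                                     "RIB")) {
  assert_that(is.character(classes) && length(classes) >= 1,
              "classes must be a non-empty character vector")
  assert_that(!anyDuplicated(classes), "class names must be unique")
  assert_that(!"background" %in% classes,
              "'background' is reserved for id 0")
  ids <- stats::setNames(seq_along(classes), classes)
  structure(
    list(classes = c(background = 0L, ids), n = length(classes)),
    class = "label_schema"
  )
}

#' @export
print.label_schema <- function(x, ...) {
  cat("label_schema:", x$n, "foreground classes + background\n")
  print(x$classes)
  invisible(x)
}

#' Look up class ids by name
#'
#' @param schema A [label_schema()].
#' @param names Character vector of class names.
#' @return Integer ids.
#' @export
schema_id <- function(schema, names) {
  stopifnot(inherits(schema, "label_schema"))
  miss <- setdiff(names, names(schema$classes))
  if (length(miss)) {
    stop("unknown label(s): ", paste(miss, collapse = ", "),
         "; valid names: ", paste(names(schema$classes), collapse = ", "),
         call. = FALSE)
  }
  unname(schema$classes[names])
}

#' Class name for each id
#' @param schema A [label_schema()].
#' @param ids Integer ids (0 = background).
#' @return Character names.
#' @export
schema_name <- function(schema, ids) {
  stopifnot(inherits(schema, "label_schema"))
  assert_that(all(ids %in% schema$classes), "id outside schema")
  names(schema$classes)[match(ids, schema$classes)]
}

#' Standard fetal abdominal ultrasound plane types
#'
#' The seven standard planes: abdominal circumference section (ACS),
#' umbilical cord section (UCS), bladder section (BHS), both-kidneys
#' horizontal section (BKHS), left kidney section (LKS), right kidney
#' section (RKS), and both-kidneys coronal section (BKCS).
#'
#' @return Character vector of the seven plane codes.
#' @export
plane_types <- function() {
  c("ACS", "UCS", "BHS", "BKHS", "LKS", "RKS", "BKCS")
}

assert_plane <- function(plane) {
  assert_that(length(plane) >= 1 && all(plane %in% plane_types()),
              paste0("plane must be one of ",
                     paste(plane_types(), collapse = ", ")))
  plane
}
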