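# Image, annotation and model I/O.
#
# Conventions used throughout the package:
#   * images are numeric matrices indexed [row, col], 1-based, with 8-bit
#     intensities in [0, 255];
#   * polygons and contours are n x 2 matrices of (row, col) vertex
#     coordinates, 1-based, implicitly closed (last vertex connects back to
#     the first).

#' Construct a grayscale image
#'
#' Thin validated wrapper around a numeric `[row, col]` matrix with 8-bit
#' intensities.
#'
#' @param pixels numeric matrix, values in `[0, 255]`.
#' @return an object of class `gray_image` (a matrix with a class attribute).
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stop("image intensities must be finite and within [0, 255]")
  structure(pixels, class = c("gray_image", "matrix"))
}

as_pixels <- function(image) {
  if (inherits(image, "gray_image")) unclass(image) else image
}

#' Load an image as 8-bit grayscale
#'
#' Reads a PNG or TIFF raster image. RGB(A) inputs are converted to 8-bit
#' luminance using the ITU-R BT.601 weights (0.299, 0.587, 0.114), rounded
#' half-up; images that are already single-channel are passed through
#' unchanged.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return a [gray_image()].
#' @export
load_gray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (PNG and TIFF are supported)")
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  if (length(arr) == 0L) stop("zero-size image: ", path)
  # readPNG/readTIFF scale to [0,1]; round half-up to 8-bit levels
  gray_image(floor(arr * 255 + 0.5))
}

#' Write a grayscale image to a PNG file
#'
#' @param image a [gray_image()] or plain matrix with values in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_gray <- function(image, path) {
  px <- as_pixels(image)
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Construct an annotation record
#'
#' One polygonal region of interest with a class label and an optional
#' semantic identifier (e.g. an ontology IRI, carried as an opaque string).
#'
#' @param polygon n x 2 matrix of (row, col) vertices, 1-based, n >= 3;
#'   implicitly closed.
#' @param label nonempty class label.
#' @param label_uri optional semantic identifier string.
#' @param image_id identifier of the image the polygon belongs to.
#' @return an object of class `annotation_record`.
#' @export
annotation_record <- function(polygon, label, label_uri = NULL, image_id = "") {
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  rec <- structure(
    list(polygon = polygon, label = label, label_uri = label_uri,
         image_id = image_id),
    class = "annotation_record")
  validate_annotation(rec)
  rec
}

validate_annotation <- function(rec, where = "annotation") {
  p <- rec$polygon
  if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L || anyNA(p))
    stop(where, ": polygon must be a numeric matrix of >= 3 (row, col) vertices")
  if (!is.character(rec$label) || length(rec$label) != 1L || !nzchar(rec$label))
    stop(where, ": label must be a nonempty string")
  if (!is.null(rec$label_uri) &&
      (!is.character(rec$label_uri) || length(rec$label_uri) != 1L))
    stop(where, ": label_uri must be a single string or NULL")
  invisible(rec)
}

#' Read polygon annotations from JSON
#'
#' The schema is a JSON object
#' `{"image_id": "...", "annotations": [{"polygon": [[row, col], ...],
#' "label": "...", "label_uri": "..."?}, ...]}` with 1-based pixel
#' coordinates. `label_uri` is optional and omitted when absent.
#'
#' @param path path to the JSON file.
#' @return list of [annotation_record()]s, in file order.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$annotations))
    stop("annotation file lacks an 'annotations' array: ", path)
  image_id <- if (is.null(doc$image_id)) "" else doc$image_id
  lapply(seq_along(doc$annotations), function(i) {
    a <- doc$annotations[[i]]
    poly <- a$polygon
    if (is.null(poly) || length(poly) < 1L)
      stop("annotation ", i, ": missing polygon")
    m <- do.call(rbind, lapply(poly, function(v) as.numeric(unlist(v))))
    if (ncol(m) != 2L)
      stop("annotation ", i, ": polygon vertices must be [row, col] pairs")
    rec <- structure(
      list(polygon = m,
           label = if (is.null(a$label)) "" else a$label,
           label_uri = a$label_uri,
           image_id = image_id),
      class = "annotation_record")
    validate_annotation(rec, where = paste0("annotation ", i,
      if (nzchar(rec$label)) paste0(" ('", rec$label, "')") else ""))
    rec
  })
}

#' Write polygon annotations to JSON
#'
#' Inverse of [read_annotations()]; `read_annotations(write_annotations(x))`
#' reproduces the record list.
#'
#' @param records list of [annotation_record()]s (may be empty).
#' @param path output path.
#' @param image_id image identifier stored at the top level; defaults to the
#'   `image_id` of the first record.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path, image_id = NULL) {
  for (i in seq_along(records)) validate_annotation(records[[i]], paste0("annotation ", i))
  if (is.null(image_id))
    image_id <- if (length(records)) records[[1]]$image_id else ""
  anns <- lapply(records, function(r) {
    out <- list(
      polygon = lapply(seq_len(nrow(r$polygon)),
                       function(i) as.numeric(r$polygon[i, ])),
      label = r$label)
    if (!is.null(r$label_uri)) out$label_uri <- r$label_uri
    out
  })
  doc <- list(image_id = image_id, annotations = anns)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Pixel calibration
#'
#' @param microns_per_pixel physical size of one pixel side, in micrometres;
#'   strictly positive.
#' @return an object of class `calibration`.
#' @export
calibration <- function(microns_per_pixel) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be a single positive number")
  structure(list(microns_per_pixel = microns_per_pixel), class = "calibration")
}

MODEL_FORMAT <- "textsnake-maxmargin-v1"

serialize_binary_model <- function(m) {
  list(
    support_vectors = apply(m$support_vectors, 1, as.numeric, simplify = FALSE),
    multipliers = as.numeric(m$multipliers),
    sv_labels = as.integer(m$sv_labels),
    bias = m$bias,
    dual_objective = m$dual_objective,
    kernel = m$kernel[!vapply(m$kernel, is.null, logical(1))],
    cost = m$cost,
    dim = m$dim)
}

deserialize_binary_model <- function(s) {
  sv <- do.call(rbind, lapply(s$support_vectors, as.numeric))
  if (is.null(sv)) sv <- matrix(numeric(0), 0, s$dim)
  structure(
    list(support_vectors = sv,
         multipliers = as.numeric(s$multipliers),
         sv_labels = as.integer(s$sv_labels),
         bias = as.numeric(s$bias),
         dual_objective = as.numeric(s$dual_objective),
         kernel = do.call(kernel_spec, s$kernel),
         cost = as.numeric(s$cost),
         dim = as.integer(s$dim)),
    class = "maxmargin_model")
}

#' Save a trained classifier to disk
#'
#' Models are stored as versioned JSON with full floating-point precision, so
#' that a reloaded model reproduces decision values to better than 1e-12
#' relative error.
#'
#' @param model a `maxmargin_model` or `maxmargin_multiclass` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path) {
  if (inherits(model, "maxmargin_model")) {
    doc <- list(format = MODEL_FORMAT, type = "binary",
                model = serialize_binary_model(model))
  } else if (inherits(model, "maxmargin_multiclass")) {
    doc <- list(
      format = MODEL_FORMAT, type = "multiclass",
      class_names = model$class_names,
      scaling = if (is.null(model$scaling)) NULL else
        list(center = as.numeric(model$scaling$center),
             scale = as.numeric(model$scaling$scale)),
      pair_names = names(model$pairwise_models),
      pairwise_models = lapply(model$pairwise_models, serialize_binary_model))
    doc <- doc[!vapply(doc, is.null, logical(1))]
  } else stop("not a textsnake model object")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' Load a classifier saved by [save_model()]
#'
#' @param path path to a model file.
#' @return the model object; errors on a version/format mismatch or a
#'   truncated file.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e)))
  if (is.null(doc$format) || !identical(doc$format, MODEL_FORMAT))
    stop("model format mismatch: expected '", MODEL_FORMAT, "', found '",
         doc$format %||% "<none>", "'")
  if (identical(doc$type, "binary")) return(deserialize_binary_model(doc$model))
  if (identical(doc$type, "multiclass")) {
    pm <- lapply(doc$pairwise_models, deserialize_binary_model)
    names(pm) <- unlist(doc$pair_names)
    scaling <- if (is.null(doc$scaling)) NULL else
      list(center = as.numeric(unlist(doc$scaling$center)),
           scale = as.numeric(unlist(doc$scaling$scale)))
    return(structure(
      list(class_names = unlist(doc$class_names),
           pairwise_models = pm, scaling = scaling),
      class = "maxmargin_multiclass"))
  }
  stop("unknown model type in ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
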