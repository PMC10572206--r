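# Annotated-image records and Pascal VOC (labelImg dialect) I/O.
#
# A record bundles the pixel array with its annotation table. Internally all
# coordinates are 0-based half-open; VOC XML stores 1-based inclusive pixel
# indices, so reading subtracts 1 from xmin/ymin and writing adds it back
# (xmax/ymax are unchanged by the convention switch).

empty_annotations <- function() {
  tibble(
    label = character(), xmin = numeric(), ymin = numeric(),
    xmax = numeric(), ymax = numeric(), difficult = logical()
  )
}

#' Construct an annotated image record
#'
#' @param id Character image identifier, unique within a dataset.
#' @param pixels Numeric array `height x width x 3` with values in \[0, 1\].
#' @param annotations Tibble with columns label, xmin, ymin, xmax, ymax,
#'   difficult (0-based half-open pixel coordinates). May be empty.
#' @return An object of class `grain_record`.
#' @export
image_record <- function(id, pixels, annotations = empty_annotations()) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  ann <- as_tibble(annotations)
  if (nrow(ann) == 0L) ann <- empty_annotations()
  ann <- ann[, c("label", "xmin", "ymin", "xmax", "ymax", "difficult")]
  h <- dim(pixels)[1]
  w <- dim(pixels)[2]
  if (nrow(ann) > 0L) {
    assert_valid_boxes(box_matrix(ann), "annotation box")
    inside <- ann$xmin >= 0 & ann$ymin >= 0 & ann$xmax <= w & ann$ymax <= h
    if (any(!inside & !ann$difficult)) {
      abort("non-difficult annotation boxes must lie inside the image")
    }
  }
  structure(
    list(id = as.character(id), width = w, height = h,
         pixels = pixels, annotations = ann),
    class = "grain_record"
  )
}

#' @export
print.grain_record <- function(x, ...) {
  cat(sprintf(
    "<grain_record '%s'> %dx%d px, %d annotation(s) (%d difficult)\n",
    x$id, x$width, x$height, nrow(x$annotations), sum(x$annotations$difficult)
  ))
  invisible(x)
}

xml_num <- function(node, xpath, context) {
  el <- xml2::xml_find_first(node, xpath)
  if (inherits(el, "xml_missing")) {
    abort(sprintf("VOC parse error: missing element '%s' in %s", xpath, context))
  }
  v <- suppressWarnings(as.numeric(xml2::xml_text(el)))
  if (is.na(v)) {
    abort(sprintf("VOC parse error: element '%s' in %s is not numeric", xpath, context))
  }
  v
}

#' Read a labelImg/Pascal-VOC annotation with its image
#'
#' Parses `object/name`, `object/bndbox/xmin..ymax` and the optional
#' `object/difficult` flag, converts the 1-based inclusive VOC coordinates to
#' the package's 0-based half-open convention, and checks that the XML `size`
#' element matches the decoded image.
#'
#' @param xml_path Path to the labelImg XML file.
#' @param image_path Path to the PNG image; defaults to the `path`/`filename`
#'   recorded in the XML, resolved relative to the XML's directory.
#' @return A `grain_record`.
#' @export
read_voc_xml <- function(xml_path, image_path = NULL) {
  doc <- xml2::read_xml(xml_path)
  if (is.null(image_path)) {
    fn <- xml2::xml_find_first(doc, "./filename")
    if (inherits(fn, "xml_missing")) {
      abort("VOC parse error: missing element 'filename' and no image_path given")
    }
    image_path <- file.path(dirname(xml_path), xml2::xml_text(fn))
  }
  pixels <- read_image(image_path)
  w <- xml_num(doc, "./size/width", xml_path)
  h <- xml_num(doc, "./size/height", xml_path)
  if (w != dim(pixels)[2] || h != dim(pixels)[1]) {
    abort(sprintf(
      "VOC consistency error: XML size %dx%d does not match image %dx%d",
      w, h, dim(pixels)[2], dim(pixels)[1]
    ))
  }
  objs <- xml2::xml_find_all(doc, "./object")
  ann <- purrr::map_dfr(objs, function(o) {
    name <- xml2::xml_find_first(o, "./name")
    if (inherits(name, "xml_missing")) {
      abort(sprintf("VOC parse error: missing element 'name' in %s", xml_path))
    }
    diff <- xml2::xml_find_first(o, "./difficult")
    difficult <- !inherits(diff, "xml_missing") && xml2::xml_text(diff) == "1"
    tibble(
      label = xml2::xml_text(name),
      xmin = xml_num(o, "./bndbox/xmin", xml_path) - 1,
      ymin = xml_num(o, "./bndbox/ymin", xml_path) - 1,
      xmax = xml_num(o, "./bndbox/xmax", xml_path),
      ymax = xml_num(o, "./bndbox/ymax", xml_path),
      difficult = difficult
    )
  })
  if (length(objs) == 0L) ann <- empty_annotations()
  id <- tools::file_path_sans_ext(basename(xml_path))
  image_record(id, pixels, ann)
}

#' Write a record's annotations as labelImg-compatible VOC XML
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' inclusive VOC convention, so `read_voc_xml(write_voc_xml(r))` round-trips
#' exactly.
#'
#' @param record A `grain_record`.
#' @param xml_path Output XML path.
#' @param image_filename The image file name stored in the XML; defaults to
#'   `<id>.png`.
#' @return `xml_path`, invisibly.
#' @export
write_voc_xml <- function(record, xml_path, image_filename = NULL) {
  stopifnot(inherits(record, "grain_record"))
  ann <- record$annotations
  if (nrow(ann) > 0L) {
    inside <- ann$xmin >= 0 & ann$ymin >= 0 &
      ann$xmax <= record$width & ann$ymax <= record$height
    if (!all(inside)) {
      abort("refusing to write VOC XML: annotation box outside image bounds")
    }
  }
  if (is.null(image_filename)) image_filename <- paste0(record$id, ".png")
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", ".")
  xml2::xml_add_child(doc, "filename", image_filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(record$width))
  xml2::xml_add_child(size, "height", as.character(record$height))
  xml2::xml_add_child(size, "depth", "3")
  xml2::xml_add_child(doc, "segmented", "0")
  fmt <- function(v) {
    # integral coordinates (the labelImg norm) written without decimal point
    if (abs(v - round(v)) < 1e-9) sprintf("%d", as.integer(round(v))) else
      sprintf("%.3f", v)
  }
  for (i in seq_len(nrow(ann))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", ann$label[i])
    xml2::xml_add_child(o, "pose", "Unspecified")
    xml2::xml_add_child(o, "truncated", "0")
    xml2::xml_add_child(o, "difficult", if (ann$difficult[i]) "1" else "0")
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", fmt(ann$xmin[i] + 1))
    xml2::xml_add_child(bb, "ymin", fmt(ann$ymin[i] + 1))
    xml2::xml_add_child(bb, "xmax", fmt(ann$xmax[i]))
    xml2::xml_add_child(bb, "ymax", fmt(ann$ymax[i]))
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

#' Read a PNG image as an H x W x 3 array in \[0, 1\]
#' @param path Image path.
#' @return Numeric array `height x width x 3`.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  px
}

#' Write an H x W x 3 array in \[0, 1\] as PNG
#' @param pixels Image array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels, 0), 1), path)
  invisible(path)
}

#' Flatten records' annotations into one tidy table
#'
#' @param records A list of `grain_record`s (or a single record).
#' @return Tibble with columns image_id, label, xmin, ymin, xmax, ymax,
#'   difficult.
#' @export
flatten_annotations <- function(records) {
  if (inherits(records, "grain_record")) records <- list(records)
  out <- purrr::map_dfr(records, function(r) {
    n <- nrow(r$annotations)
    dplyr::bind_cols(tibble(image_id = rep(r$id, n)), r$annotations)
  })
  if (nrow(out) == 0L) {
    out <- dplyr::bind_cols(tibble(image_id = character()), empty_annotations())
  }
  out
}

#' Read a dataset manifest and load its records
#'
#' A manifest is a tab-separated text file with columns `image` and `xml`
#' (paths relative to the manifest's directory) as written by
#' [generate_dataset()].
#'
#' @param manifest_path Path to manifest.tsv.
#' @return List of `grain_record`s.
#' @export
load_dataset <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  purrr::map(seq_len(nrow(man)), function(i) {
    read_voc_xml(file.path(base, man$xml[i]), file.path(base, man$image[i]))
  })
}
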