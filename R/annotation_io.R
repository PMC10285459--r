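#' Annotation records
#'
#' An annotation record holds one image's ground-truth instances: the image
#' identifier, the pixel size of the image, and the instance boxes (an
#' `rbox` for rotated records or an `hbox` for horizontal records). There
#' is a single foreground class (the damage symptom), so no per-instance
#' labels are stored.
#'
#' @param image_id Character image identifier (usually the file stem).
#' @param image_size Integer vector `c(width, height)` in pixels.
#' @param instances An `rbox` or `hbox` with zero or more rows.
#' @param source_path Optional path the record was read from.
#' @return An `annotation_record` list.
#' @export
annotation_record <- function(image_id, image_size, instances,
                              source_path = NA_character_) {
  stopifnot(length(image_size) == 2, all(image_size > 0))
  if (!inherits(instances, "rbox") && !inherits(instances, "hbox"))
    stop("instances must be an rbox or hbox", call. = FALSE)
  structure(list(image_id = as.character(image_id),
                 image_size = as.numeric(image_size),
                 instances = instances,
                 source_path = source_path),
            class = "annotation_record")
}

#' @export
print.annotation_record <- function(x, ...) {
  kind <- if (inherits(x$instances, "rbox")) "rotated" else "horizontal"
  cat(sprintf("<annotation_record> %s (%dx%d), %d %s instance(s)\n",
              x$image_id, x$image_size[1], x$image_size[2],
              nrow(x$instances), kind))
  invisible(x)
}

n_instances <- function(record) nrow(record$instances)

xml_num <- function(node, name, path) {
  child <- xml2::xml_find_first(node, name)
  if (inherits(child, "xml_missing"))
    stop(sprintf("missing <%s> node in %s", name, path), call. = FALSE)
  v <- suppressWarnings(as.numeric(xml2::xml_text(child)))
  if (is.na(v))
    stop(sprintf("non-numeric <%s> in %s", name, path), call. = FALSE)
  v
}

#' Read a roLabelImg annotation file
#'
#' Parses the roLabelImg XML dialect: `annotation/object/robndbox` nodes
#' carrying `cx, cy, w, h, angle`. The stored angle is the rotation of the
#' stored `w` edge in radians, clockwise from the x-axis, with period `pi`;
#' on read every box is canonicalized into the long-edge convention
#' (`w >= h`, theta in `[-pi/4, 3*pi/4)`), so the in-memory representation
#' is single-valued regardless of how the annotator stored the box.
#' Instance order in the file is preserved.
#'
#' @param xml_path Path to the XML file.
#' @return An `annotation_record` with rotated instances.
#' @export
read_rolabelimg <- function(xml_path) {
  doc <- xml2::read_xml(xml_path)
  size_node <- xml2::xml_find_first(doc, "./size")
  if (inherits(size_node, "xml_missing"))
    stop(sprintf("missing <size> node in %s", xml_path), call. = FALSE)
  wd <- xml_num(size_node, "width", xml_path)
  ht <- xml_num(size_node, "height", xml_path)
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  boxes <- xml2::xml_find_all(doc, "./object/robndbox")
  if (length(boxes) == 0L) {
    inst <- empty_rbox()
  } else {
    vals <- vapply(boxes, function(nd) {
      c(xml_num(nd, "cx", xml_path), xml_num(nd, "cy", xml_path),
        xml_num(nd, "w", xml_path), xml_num(nd, "h", xml_path),
        xml_num(nd, "angle", xml_path))
    }, numeric(5))
    inst <- rbox(vals[1, ], vals[2, ], vals[3, ], vals[4, ], vals[5, ])
  }
  annotation_record(image_id = sub("\\.[^.]*$", "", basename(
                      if (is.na(fname) || fname == "") xml_path else fname)),
                    image_size = c(wd, ht), instances = inst,
                    source_path = xml_path)
}

empty_rbox <- function() {
  structure(matrix(numeric(0), ncol = 5,
                   dimnames = list(NULL, c("x", "y", "w", "h", "theta"))),
            class = c("rbox", "matrix", "array"))
}

#' Write a roLabelImg annotation file
#'
#' Serializes a rotated record into the roLabelImg XML dialect. Angles are
#' stored in `[0, pi)` (the long-edge theta wrapped by the period `pi`), so
#' a write-read round trip reproduces every canonical box field to within
#' 1e-6.
#'
#' @param record An `annotation_record` with rotated instances.
#' @param xml_path Output path.
#' @return Invisibly, `xml_path`.
#' @export
write_rolabelimg <- function(record, xml_path) {
  stopifnot(inherits(record, "annotation_record"),
            inherits(record$instances, "rbox"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", paste0(record$image_id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(record$image_size[1]))
  xml2::xml_add_child(size, "height", format(record$image_size[2]))
  xml2::xml_add_child(size, "depth", "3")
  b <- record$instances
  for (i in seq_len(nrow(b))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "type", "robndbox")
    xml2::xml_add_child(obj, "name", "damage_symptom")
    rb <- xml2::xml_add_child(obj, "robndbox")
    stored_angle <- b[i, "theta"] %% pi
    xml2::xml_add_child(rb, "cx", format(b[i, "x"], digits = 12))
    xml2::xml_add_child(rb, "cy", format(b[i, "y"], digits = 12))
    xml2::xml_add_child(rb, "w", format(b[i, "w"], digits = 12))
    xml2::xml_add_child(rb, "h", format(b[i, "h"], digits = 12))
    xml2::xml_add_child(rb, "angle", format(stored_angle, digits = 12))
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

#' Read a labelImg (PASCAL-VOC style) annotation file
#'
#' Parses `annotation/object/bndbox` nodes with `xmin, ymin, xmax, ymax`.
#'
#' @param xml_path Path to the XML file.
#' @return An `annotation_record` with horizontal instances.
#' @export
read_labelimg <- function(xml_path) {
  doc <- xml2::read_xml(xml_path)
  size_node <- xml2::xml_find_first(doc, "./size")
  wd <- xml_num(size_node, "width", xml_path)
  ht <- xml_num(size_node, "height", xml_path)
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  boxes <- xml2::xml_find_all(doc, "./object/bndbox")
  if (length(boxes) == 0L) {
    inst <- structure(matrix(numeric(0), ncol = 4,
                             dimnames = list(NULL, c("x1", "y1", "x2", "y2"))),
                      class = c("hbox", "matrix", "array"))
  } else {
    vals <- vapply(boxes, function(nd) {
      c(xml_num(nd, "xmin", xml_path), xml_num(nd, "ymin", xml_path),
        xml_num(nd, "xmax", xml_path), xml_num(nd, "ymax", xml_path))
    }, numeric(4))
    inst <- hbox(vals[1, ], vals[2, ], vals[3, ], vals[4, ])
  }
  annotation_record(image_id = sub("\\.[^.]*$", "", basename(
                      if (is.na(fname) || fname == "") xml_path else fname)),
                    image_size = c(wd, ht), instances = inst,
                    source_path = xml_path)
}

#' Write a labelImg (PASCAL-VOC style) annotation file
#'
#' @param record An `annotation_record` with horizontal instances.
#' @param xml_path Output path.
#' @return Invisibly, `xml_path`.
#' @export
write_labelimg <- function(record, xml_path) {
  stopifnot(inherits(record, "annotation_record"),
            inherits(record$instances, "hbox"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", paste0(record$image_id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(record$image_size[1]))
  xml2::xml_add_child(size, "height", format(record$image_size[2]))
  xml2::xml_add_child(size, "depth", "3")
  b <- record$instances
  for (i in seq_len(nrow(b))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", "damage_symptom")
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(b[i, "x1"], digits = 12))
    xml2::xml_add_child(bb, "ymin", format(b[i, "y1"], digits = 12))
    xml2::xml_add_child(bb, "xmax", format(b[i, "x2"], digits = 12))
    xml2::xml_add_child(bb, "ymax", format(b[i, "y2"], digits = 12))
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

#' Derive a horizontal record from a rotated one
#'
#' Replaces every rotated instance by its horizontal circumscribed
#' rectangle, preserving instance count and order. This is how a
#' horizontal-box dataset is derived from rotated annotations for fair
#' comparison of horizontal and rotated detectors. Boxes are not clipped to
#' the image bounds by default, since circumscription of a truncated
#' symptom may legitimately extend past the frame; set `clip = TRUE` to
#' intersect with the image rectangle.
#'
#' @param record An `annotation_record` with rotated instances.
#' @param clip Clip circumscribed boxes to the image bounds.
#' @return An `annotation_record` with horizontal instances.
#' @export
convert_to_horizontal <- function(record, clip = FALSE) {
  stopifnot(inherits(record, "annotation_record"),
            inherits(record$instances, "rbox"))
  b <- record$instances
  if (nrow(b) == 0L) {
    hb <- structure(matrix(numeric(0), ncol = 4,
                           dimnames = list(NULL, c("x1", "y1", "x2", "y2"))),
                    class = c("hbox", "matrix", "array"))
  } else {
    hb <- circumscribed_hbb(b)
    if (clip) {
      hb[, "x1"] <- pmax(hb[, "x1"], 0)
      hb[, "y1"] <- pmax(hb[, "y1"], 0)
      hb[, "x2"] <- pmin(hb[, "x2"], record$image_size[1])
      hb[, "y2"] <- pmin(hb[, "y2"], record$image_size[2])
    }
  }
  annotation_record(record$image_id, record$image_size, hb,
                    record$source_path)
}

#' Read every annotation file in a directory
#'
#' @param dir Directory containing `.xml` files.
#' @param dialect `"rolabelimg"` (rotated) or `"labelimg"` (horizontal).
#' @return A list of `annotation_record`s, sorted by file name.
#' @export
read_annotation_dir <- function(dir, dialect = c("rolabelimg", "labelimg")) {
  dialect <- match.arg(dialect)
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  reader <- if (dialect == "rolabelimg") read_rolabelimg else read_labelimg
  lapply(files, reader)
}
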