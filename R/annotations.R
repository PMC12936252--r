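# Annotation domain model: per-image tooth annotations for the four maxillary
# incisors, in either the keypoint ("pose") or the crown/root bounding-box
# ("detect") dialect of the YOLO label format.
#
# Coordinate convention: origin at the top-left corner of the radiograph,
# x rightward, y downward, continuous pixel units (sub-pixel positions are
# allowed). Label files store coordinates normalized to [0, 1] by the image
# width/height.

# FDI codes of the four maxillary incisors, in image order (patient's right
# lateral first). Pose class index i maps to .TOOTH_CODES[i + 1]; detect class
# index is tooth_index * 2 + region_index with crown = 0, root = 1.
.TOOTH_CODES <- c(12L, 11L, 21L, 22L)
.KEYPOINT_ROLES <- c("incisal", "cervical", "apex")

#' Image frame of a radiograph
#'
#' Holds the pixel dimensions of a panoramic radiograph, needed to convert
#' between pixel coordinates and the normalized coordinates stored in label
#' files.
#'
#' @param width,height Image dimensions in pixels; must be >= 1.
#' @return An object of class `image_frame` with elements `width` and
#'   `height`.
#' @examples
#' image_frame(2900, 1500)
#' @export
image_frame <- function(width, height) {
  if (!is.numeric(width) || !is.numeric(height) || length(width) != 1L ||
      length(height) != 1L || !is.finite(width) || !is.finite(height) ||
      width < 1 || height < 1) {
    stop("invalid frame: width and height must be finite numbers >= 1",
         call. = FALSE)
  }
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame %g x %g px>\n", x$width, x$height))
  invisible(x)
}

#' Normalize a pixel coordinate by an image extent
#'
#' Maps a pixel coordinate to the unit interval by dividing by the image
#' width (for x) or height (for y), as used in YOLO-style label files.
#'
#' @param value Pixel coordinate(s), each in `[0, extent]`.
#' @param extent Image extent in pixels (> 0).
#' @return `value / extent`, in `[0, 1]`.
#' @examples
#' normalize_coordinate(320, 640)   # 0.5
#' @export
normalize_coordinate <- function(value, extent) {
  if (!is.numeric(extent) || length(extent) != 1L || !is.finite(extent) ||
      extent <= 0) {
    stop("invalid frame: extent must be a positive number", call. = FALSE)
  }
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("coordinate must be finite numeric", call. = FALSE)
  }
  if (any(value < 0 | value > extent)) {
    stop(sprintf("coordinate out of bounds: value outside [0, %g]", extent),
         call. = FALSE)
  }
  value / extent
}

# Inverse of normalize_coordinate; internal.
denormalize_coordinate <- function(value, extent) {
  value * extent
}

tooth_code_from_pose_class <- function(class_index) {
  .TOOTH_CODES[class_index + 1L]
}

pose_class_from_tooth_code <- function(code) {
  match(code, .TOOTH_CODES) - 1L
}

new_pose_annotation <- function(tooth_code, box, keypoints) {
  structure(list(
    tooth = as.integer(tooth_code),
    class_index = pose_class_from_tooth_code(tooth_code),
    mode = "pose",
    box = box,            # c(x_center, y_center, width, height), px
    keypoints = keypoints # data.frame(role, x, y, visible), px
  ), class = "tooth_annotation")
}

new_detect_annotation <- function(tooth_code, crown_box, root_box) {
  structure(list(
    tooth = as.integer(tooth_code),
    class_index = pose_class_from_tooth_code(tooth_code),
    mode = "detect",
    crown_box = crown_box, # c(x_center, y_center, width, height), px
    root_box = root_box
  ), class = "tooth_annotation")
}

#' @export
print.tooth_annotation <- function(x, ...) {
  cat(sprintf("<tooth_annotation FDI %d, mode %s>\n", x$tooth, x$mode))
  invisible(x)
}

split_label_fields <- function(line) {
  strsplit(trimws(line), "[[:space:]]+")[[1]]
}

parse_numeric_fields <- function(fields, line_no) {
  vals <- suppressWarnings(as.numeric(fields))
  if (any(is.na(vals))) {
    stop(sprintf("parse error at line %d: non-numeric token '%s'",
                 line_no, fields[which(is.na(vals))[1]]), call. = FALSE)
  }
  vals
}

check_normalized <- function(vals, line_no) {
  if (any(vals < 0 | vals > 1)) {
    stop(sprintf("parse error at line %d: normalized value outside [0, 1]",
                 line_no), call. = FALSE)
  }
  vals
}

#' Parse YOLO pose (keypoint) label lines
#'
#' Each non-empty line has 14 whitespace-separated fields:
#' `class xc yc w h  x1 y1 v1  x2 y2 v2  x3 y3 v3`, all coordinates
#' normalized to `[0, 1]`. The three keypoints are, in order, the incisal
#' edge, the cervical margin and the root apex. Visibility flags `v` follow
#' the usual convention (0 = missing, 1 = labeled but occluded, 2 = visible);
#' keypoints with `v = 0` are flagged not visible and make the tooth
#' unmeasurable downstream.
#'
#' @param lines Character vector of label-file lines.
#' @param frame An [image_frame()]; coordinates are denormalized to pixels.
#' @return A list of pose-mode `tooth_annotation` objects, ordered by class
#'   index. An empty input yields an empty list with a warning.
#' @seealso [parse_detect_labels()], [write_pose_labels()]
#' @export
parse_pose_labels <- function(lines, frame) {
  stopifnot(inherits(frame, "image_frame"))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty pose label input: no annotations", call. = FALSE)
    return(list())
  }
  seen <- integer(0)
  anns <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- split_label_fields(lines[i])
    if (length(fields) != 14L) {
      stop(sprintf("parse error at line %d: expected 14 fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    vals <- parse_numeric_fields(fields, i)
    cls <- vals[1]
    if (cls != round(cls) || cls < 0 || cls > 3) {
      stop(sprintf("unknown class %g at line %d: pose classes are 0-3",
                   cls, i), call. = FALSE)
    }
    cls <- as.integer(cls)
    if (cls %in% seen) {
      stop(sprintf("duplicate tooth: class %d appears twice (line %d)",
                   cls, i), call. = FALSE)
    }
    seen <- c(seen, cls)
    check_normalized(vals[2:5], i)
    kp <- matrix(vals[6:14], ncol = 3, byrow = TRUE)  # x, y, v per keypoint
    check_normalized(kp[, 1:2], i)
    if (any(!kp[, 3] %in% c(0, 1, 2))) {
      stop(sprintf("parse error at line %d: visibility flag must be 0, 1 or 2",
                   i), call. = FALSE)
    }
    box <- c(x_center = denormalize_coordinate(vals[2], frame$width),
             y_center = denormalize_coordinate(vals[3], frame$height),
             width = denormalize_coordinate(vals[4], frame$width),
             height = denormalize_coordinate(vals[5], frame$height))
    keypoints <- data.frame(
      role = .KEYPOINT_ROLES,
      x = denormalize_coordinate(kp[, 1], frame$width),
      y = denormalize_coordinate(kp[, 2], frame$height),
      visible = kp[, 3] > 0,
      stringsAsFactors = FALSE
    )
    anns[[i]] <- new_pose_annotation(tooth_code_from_pose_class(cls), box,
                                     keypoints)
  }
  anns[order(vapply(anns, `[[`, integer(1), "class_index"))]
}

#' Parse YOLO detection (bounding-box) label lines
#'
#' Each line has 5 fields `class xc yc w h` with normalized coordinates.
#' The 8 detect classes encode (tooth, region) pairs:
#' `class = tooth_index * 2 + region_index`, tooth index 0-3 over FDI
#' 12, 11, 21, 22 and region index 0 = crown, 1 = root. Crown and root boxes
#' are paired per tooth; a tooth missing either box is an error.
#'
#' @inheritParams parse_pose_labels
#' @return A list of 4 detect-mode `tooth_annotation` objects (crown + root
#'   box each), ordered by tooth.
#' @export
parse_detect_labels <- function(lines, frame) {
  stopifnot(inherits(frame, "image_frame"))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty detect label input: no annotations", call. = FALSE)
    return(list())
  }
  boxes <- vector("list", 8L)
  for (i in seq_along(lines)) {
    fields <- split_label_fields(lines[i])
    if (length(fields) != 5L) {
      stop(sprintf("parse error at line %d: expected 5 fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    vals <- parse_numeric_fields(fields, i)
    cls <- vals[1]
    if (cls != round(cls) || cls < 0 || cls > 7) {
      stop(sprintf("unknown class %g at line %d: detect classes are 0-7",
                   cls, i), call. = FALSE)
    }
    cls <- as.integer(cls)
    if (!is.null(boxes[[cls + 1L]])) {
      stop(sprintf("duplicate box: class %d appears twice (line %d)",
                   cls, i), call. = FALSE)
    }
    check_normalized(vals[2:5], i)
    boxes[[cls + 1L]] <- c(
      x_center = denormalize_coordinate(vals[2], frame$width),
      y_center = denormalize_coordinate(vals[3], frame$height),
      width = denormalize_coordinate(vals[4], frame$width),
      height = denormalize_coordinate(vals[5], frame$height))
  }
  anns <- list()
  for (ti in 0:3) {
    crown <- boxes[[ti * 2L + 1L]]
    root <- boxes[[ti * 2L + 2L]]
    code <- .TOOTH_CODES[ti + 1L]
    if (is.null(crown) || is.null(root)) {
      missing_region <- if (is.null(crown)) "crown" else "root"
      if (is.null(crown) && is.null(root)) next  # tooth absent entirely
      stop(sprintf("incomplete tooth: FDI %d is missing its %s box",
                   code, missing_region), call. = FALSE)
    }
    anns[[length(anns) + 1L]] <- new_detect_annotation(code, crown, root)
  }
  if (length(anns) == 0L) {
    stop("incomplete annotation set: no complete crown/root pair found",
         call. = FALSE)
  }
  anns
}

fmt6 <- function(x) sprintf("%.6f", x)

check_in_frame <- function(norm_vals) {
  # serialization refuses coordinates outside the frame
  if (any(norm_vals < 0 | norm_vals > 1)) {
    stop("refusing to serialize: coordinate outside image frame",
         call. = FALSE)
  }
  norm_vals
}

#' Serialize pose annotations to YOLO label lines
#'
#' Coordinates are normalized by the frame and written with 6 decimals, so a
#' parse/write round trip reproduces normalized coordinates to within 1e-6.
#' Serialization refuses coordinates outside the frame.
#'
#' @param annotations List of pose-mode `tooth_annotation` objects.
#' @param frame An [image_frame()].
#' @return Character vector of label lines, one per tooth.
#' @export
write_pose_labels <- function(annotations, frame) {
  stopifnot(inherits(frame, "image_frame"))
  vapply(annotations, function(a) {
    if (a$mode != "pose") stop("write_pose_labels needs pose annotations",
                               call. = FALSE)
    box <- check_in_frame(c(a$box[["x_center"]] / frame$width,
                            a$box[["y_center"]] / frame$height,
                            a$box[["width"]] / frame$width,
                            a$box[["height"]] / frame$height))
    kx <- check_in_frame(a$keypoints$x / frame$width)
    ky <- check_in_frame(a$keypoints$y / frame$height)
    v <- ifelse(a$keypoints$visible, 2L, 0L)
    paste(c(a$class_index, fmt6(box),
            as.vector(rbind(fmt6(kx), fmt6(ky), v))), collapse = " ")
  }, character(1))
}

#' Serialize detect annotations to YOLO label lines
#'
#' @inheritParams write_pose_labels
#' @return Character vector of label lines, two (crown, root) per tooth.
#' @export
write_detect_labels <- function(annotations, frame) {
  stopifnot(inherits(frame, "image_frame"))
  out <- character(0)
  for (a in annotations) {
    if (a$mode != "detect") stop("write_detect_labels needs detect annotations",
                                 call. = FALSE)
    ti <- a$class_index
    for (ri in 0:1) {
      b <- if (ri == 0L) a$crown_box else a$root_box
      norm <- check_in_frame(c(b[["x_center"]] / frame$width,
                               b[["y_center"]] / frame$height,
                               b[["width"]] / frame$width,
                               b[["height"]] / frame$height))
      out <- c(out, paste(c(ti * 2L + ri, fmt6(norm)), collapse = " "))
    }
  }
  out
}

#' Serialize annotations in either dialect
#'
#' Thin dispatcher over [write_pose_labels()] and [write_detect_labels()].
#'
#' @inheritParams write_pose_labels
#' @param mode `"pose"` or `"detect"`.
#' @export
write_labels <- function(annotations, frame, mode = c("pose", "detect")) {
  mode <- match.arg(mode)
  if (mode == "pose") write_pose_labels(annotations, frame)
  else write_detect_labels(annotations, frame)
}

#' Read a label file from disk
#'
#' @param path Path to a YOLO label `.txt` file.
#' @param frame An [image_frame()].
#' @param mode `"pose"` or `"detect"`.
#' @return A list of `tooth_annotation` objects.
#' @export
read_labels <- function(path, frame, mode = c("pose", "detect")) {
  mode <- match.arg(mode)
  lines <- readLines(path, warn = FALSE)
  if (mode == "pose") parse_pose_labels(lines, frame)
  else parse_detect_labels(lines, frame)
}
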