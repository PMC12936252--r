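# Crown/root length measurement and crown-referenced resorption computation.
#
# All lengths are in pixel units of the image they were measured on. Because
# every downstream quantity is a within-image ratio (correction factor) or a
# corrected ratio (resorption percent), the pixel unit cancels and no
# millimeter calibration is needed. Lengths are computed in pixel space, not
# on normalized coordinates: Euclidean distance on anisotropically normalized
# coordinates would mix the x and y scales.

euclid <- function(p, q) sqrt(sum((p - q)^2))

kp_xy <- function(ann, role) {
  i <- match(role, ann$keypoints$role)
  c(ann$keypoints$x[i], ann$keypoints$y[i])
}

#' Crown and root lengths from keypoints
#'
#' Crown length is the Euclidean distance from the incisal edge to the
#' cervical margin; root length is the distance from the cervical margin to
#' the root apex. Both are in pixels of the annotated image.
#'
#' @param annotation A pose-mode `tooth_annotation` with all three keypoints
#'   visible.
#' @return A list with `crown_length` and `root_length` (pixels).
#' @export
lengths_from_pose <- function(annotation) {
  stopifnot(inherits(annotation, "tooth_annotation"))
  if (annotation$mode != "pose") {
    stop("lengths_from_pose requires a pose-mode annotation", call. = FALSE)
  }
  if (!all(annotation$keypoints$visible)) {
    stop(sprintf("unmeasurable tooth FDI %d: missing keypoint (%s)",
                 annotation$tooth,
                 paste(annotation$keypoints$role[!annotation$keypoints$visible],
                       collapse = ", ")), call. = FALSE)
  }
  crown <- euclid(kp_xy(annotation, "incisal"), kp_xy(annotation, "cervical"))
  root <- euclid(kp_xy(annotation, "cervical"), kp_xy(annotation, "apex"))
  if (crown <= 0 || root <= 0) {
    stop(sprintf("degenerate geometry for tooth FDI %d: zero-length segment",
                 annotation$tooth), call. = FALSE)
  }
  list(crown_length = crown, root_length = root)
}

#' Crown and root lengths from bounding boxes
#'
#' The vertical dimension (height) of the crown and root boxes estimates the
#' respective lengths; this mirrors how axis-aligned region boxes are used
#' when no landmark is available, and is the source of the larger
#' measurement error of box-based pipelines on angulated teeth.
#'
#' @param annotation A detect-mode `tooth_annotation` with crown and root
#'   boxes.
#' @return A list with `crown_length` and `root_length` (pixels).
#' @export
lengths_from_boxes <- function(annotation) {
  stopifnot(inherits(annotation, "tooth_annotation"))
  if (annotation$mode != "detect") {
    stop("lengths_from_boxes requires a detect-mode annotation", call. = FALSE)
  }
  crown <- annotation$crown_box[["height"]]
  root <- annotation$root_box[["height"]]
  if (!is.finite(crown) || !is.finite(root) || crown <= 0 || root <= 0) {
    stop(sprintf("degenerate box for tooth FDI %d: non-positive height",
                 annotation$tooth), call. = FALSE)
  }
  list(crown_length = crown, root_length = root)
}

#' Crown-based magnification correction factor
#'
#' Ratio of the pre-treatment to the post-treatment crown length. Under the
#' clinical assumption that root resorption never shortens the crown, any
#' change in measured crown length between the two radiographs reflects
#' magnification/projection differences, and this ratio captures them.
#'
#' @param initial_crown,post_crown Crown lengths in pixels (> 0).
#' @return `initial_crown / post_crown` (dimensionless).
#' @export
correction_factor <- function(initial_crown, post_crown) {
  if (any(!is.finite(initial_crown)) || any(!is.finite(post_crown)) ||
      any(initial_crown <= 0) || any(post_crown <= 0)) {
    stop("correction_factor: crown lengths must be positive and finite",
         call. = FALSE)
  }
  initial_crown / post_crown
}

#' Magnification-corrected final root length
#'
#' Rescales the measured post-treatment root length into the pre-treatment
#' image's scale. The default multiplies by the correction factor
#' (pre-crown / post-crown): if the post image is uniformly magnified by m,
#' both post lengths carry the factor m, so the correction cancels it
#' exactly. `formula = "printed"` instead divides by the correction factor —
#' a convention occasionally seen in print which amplifies rather than
#' cancels a scale change; it is provided for comparison only.
#'
#' @param measured_post_root Post-treatment root length, pixels (> 0).
#' @param cf Correction factor from [correction_factor()] (> 0).
#' @param formula `"scale_cancelling"` (default) or `"printed"`.
#' @return Corrected final root length in pre-treatment pixel scale.
#' @export
corrected_final_root <- function(measured_post_root, cf,
                                 formula = c("scale_cancelling", "printed")) {
  formula <- match.arg(formula)
  if (any(!is.finite(measured_post_root)) || any(!is.finite(cf)) ||
      any(measured_post_root <= 0) || any(cf <= 0)) {
    stop("corrected_final_root: inputs must be positive and finite",
         call. = FALSE)
  }
  if (formula == "scale_cancelling") measured_post_root * cf
  else measured_post_root / cf
}

#' Percentage root resorption
#'
#' Relative root-length loss, referenced to the pre-treatment root length of
#' the same tooth. Negative values (apparent lengthening under measurement
#' noise) are retained, not clipped, so error analyses see signed errors;
#' grading treats them as Grade 0.
#'
#' @param initial_root Pre-treatment root length, pixels (> 0).
#' @param corrected_final_root Corrected post-treatment root length, pixels.
#' @return `(initial_root - corrected_final_root) / initial_root * 100`, in
#'   percent; never exceeds 100 for a positive corrected length.
#' @export
resorption_percent <- function(initial_root, corrected_final_root) {
  if (any(!is.finite(initial_root)) || any(initial_root <= 0)) {
    stop("resorption_percent: initial root length must be positive",
         call. = FALSE)
  }
  (initial_root - corrected_final_root) / initial_root * 100
}

measure_one_tooth <- function(pre_ann, post_ann, mode, formula) {
  lengths <- if (mode == "pose") lengths_from_pose else lengths_from_boxes
  pre <- lengths(pre_ann)
  post <- lengths(post_ann)
  cf <- correction_factor(pre$crown_length, post$crown_length)
  corr <- corrected_final_root(post$root_length, cf, formula)
  list(pre_crown = pre$crown_length, pre_root = pre$root_length,
       post_crown = post$crown_length, post_root = post$root_length,
       correction_factor = cf, corrected_final_root = corr,
       resorption_percent = resorption_percent(pre$root_length, corr))
}

#' Measure resorption for all teeth of one patient
#'
#' Pairs pre- and post-treatment annotations by tooth and computes, per
#' tooth, both lengths at both timepoints, the correction factor, the
#' corrected final root length and the resorption percentage. Teeth that are
#' unmeasurable at either timepoint (missing keypoint, degenerate geometry,
#' absent annotation) are reported as skipped with a reason rather than
#' failing the patient.
#'
#' @param pre_annotations,post_annotations Annotation lists for the two
#'   timepoints, both in the same mode.
#' @param mode `"pose"` or `"detect"`.
#' @param formula Correction convention, see [corrected_final_root()].
#' @return A data.frame with one row per tooth: `tooth`, `mode`, the four
#'   lengths, `correction_factor`, `corrected_final_root`,
#'   `resorption_percent`, `measured` (logical) and `skip_reason`.
#' @export
measure_patient <- function(pre_annotations, post_annotations,
                            mode = c("pose", "detect"),
                            formula = c("scale_cancelling", "printed")) {
  mode <- match.arg(mode)
  formula <- match.arg(formula)
  check_mode <- function(anns, label) {
    for (a in anns) {
      if (!inherits(a, "tooth_annotation") || a$mode != mode) {
        stop(sprintf("%s annotations are not all in %s mode", label, mode),
             call. = FALSE)
      }
    }
  }
  check_mode(pre_annotations, "pre")
  check_mode(post_annotations, "post")
  by_tooth <- function(anns) {
    setNames(anns, vapply(anns, function(a) as.character(a$tooth),
                          character(1)))
  }
  pre_by <- by_tooth(pre_annotations)
  post_by <- by_tooth(post_annotations)

  rows <- lapply(.TOOTH_CODES, function(code) {
    key <- as.character(code)
    base <- data.frame(tooth = code, mode = mode, pre_crown = NA_real_,
                       pre_root = NA_real_, post_crown = NA_real_,
                       post_root = NA_real_, correction_factor = NA_real_,
                       corrected_final_root = NA_real_,
                       resorption_percent = NA_real_, measured = FALSE,
                       skip_reason = NA_character_,
                       stringsAsFactors = FALSE)
    if (is.null(pre_by[[key]]) || is.null(post_by[[key]])) {
      tp <- if (is.null(pre_by[[key]])) "pre" else "post"
      base$skip_reason <- sprintf("missing %s-treatment annotation", tp)
      return(base)
    }
    res <- tryCatch(
      measure_one_tooth(pre_by[[key]], post_by[[key]], mode, formula),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      base$skip_reason <- res
      return(base)
    }
    base[names(res)] <- res
    base$measured <- TRUE
    base
  })
  do.call(rbind, rows)
}

#' Measure a full cohort of paired patients
#'
#' Accepts either a synthetic cohort object from [generate_cohort()] (uses
#' its in-memory annotations) or a dataset directory written by
#' [generate_cohort()]/[run_simulate()] (reads the manifest and label files).
#' Patients whose label files cannot be parsed are skipped with a warning;
#' their teeth are reported as skipped rows.
#'
#' @param x A `oiearr_cohort` object or a dataset directory path.
#' @param mode `"pose"` or `"detect"`.
#' @param formula Correction convention, see [corrected_final_root()].
#' @return A data.frame as from [measure_patient()] with a leading
#'   `patient_id` column.
#' @export
measure_cohort <- function(x, mode = c("pose", "detect"),
                           formula = c("scale_cancelling", "printed")) {
  mode <- match.arg(mode)
  formula <- match.arg(formula)
  if (inherits(x, "oiearr_cohort")) {
    pairs <- lapply(x$patients, function(p) {
      list(id = p$patient_id,
           pre = p$labels[[mode]]$pre, post = p$labels[[mode]]$post)
    })
  } else if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    manifest <- read_manifest(file.path(x, "manifest.csv"))
    pairs <- load_label_pairs(x, manifest, mode)
  } else {
    stop("measure_cohort: x must be a cohort object or a dataset directory",
         call. = FALSE)
  }
  rows <- lapply(pairs, function(p) {
    if (is.character(p$error)) {
      warning(sprintf("patient %s skipped: %s", p$id, p$error), call. = FALSE)
      df <- data.frame(tooth = .TOOTH_CODES, mode = mode, pre_crown = NA_real_,
                       pre_root = NA_real_, post_crown = NA_real_,
                       post_root = NA_real_, correction_factor = NA_real_,
                       corrected_final_root = NA_real_,
                       resorption_percent = NA_real_, measured = FALSE,
                       skip_reason = p$error, stringsAsFactors = FALSE)
    } else {
      df <- measure_patient(p$pre, p$post, mode, formula)
    }
    cbind(patient_id = p$id, df, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Read per-patient label pairs from a dataset directory; parse failures are
# captured per patient, not fatal.
load_label_pairs <- function(dir, manifest, mode) {
  col <- if (mode == "pose") "label_pose" else "label_detect"
  ids <- unique(manifest$patient_id)
  lapply(ids, function(id) {
    rows <- manifest[manifest$patient_id == id, ]
    pre_row <- rows[rows$timepoint == "pre", ]
    post_row <- rows[rows$timepoint == "post", ]
    if (nrow(pre_row) != 1L || nrow(post_row) != 1L) {
      return(list(id = id, error = "patient lacks a pre/post pair"))
    }
    res <- tryCatch({
      pre <- read_labels(file.path(dir, pre_row[[col]]),
                         image_frame(pre_row$width, pre_row$height), mode)
      post <- read_labels(file.path(dir, post_row[[col]]),
                          image_frame(post_row$width, post_row$height), mode)
      list(id = id, pre = pre, post = post, error = NULL)
    }, error = function(e) list(id = id, error = conditionMessage(e)))
    res
  })
}
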