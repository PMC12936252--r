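# Shared test utilities: hand-built annotations and small geometric helpers.

make_pose_ann <- function(tooth, incisal, cervical, apex,
                          visible = c(TRUE, TRUE, TRUE)) {
  pts <- rbind(incisal, cervical, apex)
  e <- c(x1 = min(pts[, 1]) - 4, y1 = min(pts[, 2]) - 4,
         x2 = max(pts[, 1]) + 4, y2 = max(pts[, 2]) + 4)
  box <- c(x_center = (e[["x1"]] + e[["x2"]]) / 2,
           y_center = (e[["y1"]] + e[["y2"]]) / 2,
           width = e[["x2"]] - e[["x1"]], height = e[["y2"]] - e[["y1"]])
  oiearr:::new_pose_annotation(tooth, box, data.frame(
    role = c("incisal", "cervical", "apex"),
    x = pts[, 1], y = pts[, 2], visible = visible,
    stringsAsFactors = FALSE))
}

make_detect_ann <- function(tooth, crown_box, root_box) {
  oiearr:::new_detect_annotation(tooth, crown_box, root_box)
}

box_from_segment <- function(p, q, pad = 0) {
  c(x_center = (min(p[1], q[1]) + max(p[1], q[1])) / 2,
    y_center = (min(p[2], q[2]) + max(p[2], q[2])) / 2,
    width = abs(p[1] - q[1]) + 2 * pad,
    height = abs(p[2] - q[2]) + 2 * pad)
}

rotate_about <- function(p, center, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  as.numeric(center + R %*% (p - center))
}

# Four hand-built zero-noise patients is overkill; one parametric patient
# with chosen true resorptions and a uniform post magnification suffices for
# recovery tests that must not depend on the generator.
make_manual_patient <- function(true_resorption = c(0, 10, 25, 40),
                                magnification = 1.1,
                                crown_len = 110, root_len = 130,
                                theta_deg = c(-4, 1, -2, 5)) {
  codes <- c(12L, 11L, 21L, 22L)
  pre <- list(); post <- list()
  for (i in 1:4) {
    th <- theta_deg[i] * pi / 180
    u <- c(sin(th), cos(th))
    cervical <- c(1200 + i * 90, 620)
    incisal <- cervical + crown_len * u
    apex <- cervical - root_len * u
    apex_post <- cervical - root_len * (1 - true_resorption[i] / 100) * u
    pre[[i]] <- make_pose_ann(codes[i], incisal, cervical, apex)
    mag <- function(p) magnification * p
    post[[i]] <- make_pose_ann(codes[i], mag(incisal), mag(cervical),
                               mag(apex_post))
  }
  list(pre = pre, post = post, true_resorption = true_resorption)
}

random_pose_set <- function(frame) {
  codes <- c(12L, 11L, 21L, 22L)
  lapply(1:4, function(i) {
    pts <- cbind(runif(3, 0.1, 0.9) * frame$width,
                 runif(3, 0.1, 0.9) * frame$height)
    make_pose_ann(codes[i], pts[1, ], pts[2, ], pts[3, ])
  })
}

random_detect_set <- function(frame) {
  codes <- c(12L, 11L, 21L, 22L)
  rand_box <- function() {
    w <- runif(1, 10, 0.2 * frame$width)
    h <- runif(1, 10, 0.2 * frame$height)
    c(x_center = runif(1, w / 2, frame$width - w / 2),
      y_center = runif(1, h / 2, frame$height - h / 2),
      width = w, height = h)
  }
  lapply(codes, function(code) make_detect_ann(code, rand_box(), rand_box()))
}

norm_pose_coords <- function(anns, frame) {
  unlist(lapply(anns, function(a) {
    c(a$box[c("x_center", "width")] / frame$width,
      a$box[c("y_center", "height")] / frame$height,
      a$keypoints$x / frame$width, a$keypoints$y / frame$height)
  }))
}

norm_detect_coords <- function(anns, frame) {
  unlist(lapply(anns, function(a) {
    c(a$crown_box[c("x_center", "width")] / frame$width,
      a$crown_box[c("y_center", "height")] / frame$height,
      a$root_box[c("x_center", "width")] / frame$width,
      a$root_box[c("y_center", "height")] / frame$height)
  }))
}
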