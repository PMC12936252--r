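# Conversion of continuous resorption percentages into the clinical 0-3
# grade scale (no resorption / slight apical blunting / resorption up to
# one-third of root length / loss exceeding one-third).

#' Clinical grade thresholds
#'
#' Percentage cut-offs mapping continuous root resorption to grades 0-3.
#' The grade-2/3 boundary defaults to one-third of the root length (the
#' classical definition of severe resorption). The grade-0/1 and grade-1/2
#' boundaries are not standardized; the defaults take 15% as the percentage
#' analogue of the classical 2 mm cut-off on a typical 13 mm incisor root,
#' and 5% to separate measurement noise from genuine apical blunting. All
#' three values are carried in every report so graded results are never
#' ambiguous.
#'
#' @param t1 Grade-0/1 boundary, percent (default 5).
#' @param t2 Grade-1/2 boundary, percent (default 15).
#' @param t3 Grade-2/3 boundary, percent (default 100/3).
#' @return An object of class `grade_thresholds`.
#' @export
grade_thresholds <- function(t1 = 5, t2 = 15, t3 = 100 / 3) {
  if (!is.numeric(t1) || !is.numeric(t2) || !is.numeric(t3) ||
      any(!is.finite(c(t1, t2, t3))) ||
      !(0 < t1 && t1 < t2 && t2 < t3 && t3 <= 100)) {
    stop("invalid thresholds: need 0 < t1 < t2 < t3 <= 100", call. = FALSE)
  }
  structure(list(t1 = t1, t2 = t2, t3 = t3), class = "grade_thresholds")
}

#' @export
print.grade_thresholds <- function(x, ...) {
  cat(sprintf("<grade_thresholds t1=%g t2=%g t3=%g (percent)>\n",
              x$t1, x$t2, x$t3))
  invisible(x)
}

#' Grade a resorption percentage
#'
#' Step function mapping percent resorption to grades 0-3:
#' below `t1` (including negative values) is grade 0; `[t1, t2)` grade 1;
#' `[t2, t3]` grade 2; strictly above `t3` grade 3. The grade-2 interval is
#' closed at `t3` because moderate resorption extends *up to* one-third of
#' the root while severe resorption must *exceed* it.
#'
#' @param r Resorption percentage(s); must be finite.
#' @param thresholds A [grade_thresholds()] object.
#' @return Integer grade(s) in 0-3.
#' @examples
#' grade_from_percent(c(-2, 4, 10, 20, 100/3, 40), grade_thresholds())
#' @export
grade_from_percent <- function(r, thresholds = grade_thresholds()) {
  stopifnot(inherits(thresholds, "grade_thresholds"))
  if (!is.numeric(r) || any(!is.finite(r))) {
    stop("grade_from_percent: resorption percent must be finite", call. = FALSE)
  }
  g <- integer(length(r))
  g[r >= thresholds$t1] <- 1L
  g[r >= thresholds$t2] <- 2L
  g[r > thresholds$t3] <- 3L
  g
}

#' Grade a cohort measurement table
#'
#' Adds a `grade` column to a measurement table from [measure_cohort()] or
#' [measure_patient()]. Unmeasured teeth receive `NA`.
#'
#' @param measurements Data.frame with a `resorption_percent` column.
#' @param thresholds A [grade_thresholds()] object.
#' @return The input with an integer `grade` column appended.
#' @export
grade_cohort <- function(measurements, thresholds = grade_thresholds()) {
  stopifnot(is.data.frame(measurements),
            "resorption_percent" %in% names(measurements))
  r <- measurements$resorption_percent
  grade <- rep(NA_integer_, length(r))
  ok <- is.finite(r)
  grade[ok] <- grade_from_percent(r[ok], thresholds)
  measurements$grade <- grade
  measurements
}
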