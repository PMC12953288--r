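#' PDFF steatosis-grade thresholds
#'
#' The validated MRI-PDFF cut-points separating steatosis grades:
#' PDFF-S1 at 5.75%, PDFF-S2 at 15.5%, PDFF-S3 at 21.35%. A PDFF exactly at a
#' threshold takes the higher grade.
#'
#' @format Numeric vector of length 3 (percent PDFF).
#' @export
PDFF_GRADE_THRESHOLDS <- c(5.75, 15.5, 21.35)

#' Histological steatosis grade from large-droplet hepatocyte fraction
#'
#' Pathologists grade steatosis as the fraction of hepatocytes containing
#' large lipid droplets that displace the nucleus: S0 below 5%, S1 5--33%,
#' S2 34--66%, S3 above 66%. The bands are defined on integer percentages, so
#' the input is first rounded half-up to the nearest integer percent (a value
#' of 33.4 rounds to 33 and grades S1; 33.5 rounds to 34 and grades S2).
#'
#' @param pct_hepatocytes_large_ld Numeric vector, percent of hepatocytes with
#'   large droplets, in \[0, 100\].
#' @return Integer vector of grades in 0:3.
#' @examples
#' grade_histology(c(4, 5, 33.4, 34, 66, 67))
#' @export
grade_histology <- function(pct_hepatocytes_large_ld) {
  x <- pct_hepatocytes_large_ld
  if (!is.numeric(x) || anyNA(x)) {
    stop("'pct_hepatocytes_large_ld' must be numeric without NA")
  }
  if (any(x < 0 | x > 100)) {
    stop("hepatocyte fraction must lie in [0, 100]")
  }
  r <- floor(x + 0.5)  # round half-up: pathologists report integer percents
  g <- integer(length(r))
  g[r >= 5] <- 1L
  g[r >= 34] <- 2L
  g[r >= 67] <- 3L
  g
}

#' Steatosis grade from MRI proton density fat fraction
#'
#' Grades steatosis from PDFF using the validated thresholds
#' \code{\link{PDFF_GRADE_THRESHOLDS}} (5.75, 15.5, 21.35%); a value exactly on
#' a threshold takes the higher grade.
#'
#' @param pdff_pct Numeric vector of PDFF values in percent, non-negative.
#' @return Integer vector of grades in 0:3.
#' @examples
#' grade_pdff(c(1.5, 5.75, 15.49, 21.35))
#' @export
grade_pdff <- function(pdff_pct) {
  if (!is.numeric(pdff_pct) || anyNA(pdff_pct)) {
    stop("'pdff_pct' must be numeric without NA")
  }
  if (any(pdff_pct < 0)) stop("PDFF must be non-negative")
  as.integer(rowSums(outer(pdff_pct, PDFF_GRADE_THRESHOLDS, ">=")))
}

#' Histology vs PDFF grade discordance
#'
#' The primary endpoint construct: two grades are discordant when they differ
#' by at least one grade. Direction records whether MRI over- or
#' under-estimates relative to histology; magnitude is the absolute grade
#' difference.
#'
#' @param hist_grade,pdff_grade Integer vectors of grades in 0:3 (recycled to
#'   a common length).
#' @return A data.frame with columns \code{hist_grade}, \code{pdff_grade},
#'   \code{discordant} (logical), \code{magnitude} (integer) and
#'   \code{direction} (factor: concordant, mri_over, mri_under).
#' @examples
#' assess_discordance(c(0, 2, 3), c(1, 2, 1))
#' @export
assess_discordance <- function(hist_grade, pdff_grade) {
  n <- max(length(hist_grade), length(pdff_grade))
  h <- rep_len(as.integer(hist_grade), n)
  p <- rep_len(as.integer(pdff_grade), n)
  if (anyNA(h) || anyNA(p) || any(!h %in% 0:3) || any(!p %in% 0:3)) {
    stop("grades must be integers in 0:3")
  }
  d <- p - h
  direction <- factor(
    ifelse(d == 0L, "concordant", ifelse(d > 0L, "mri_over", "mri_under")),
    levels = c("concordant", "mri_over", "mri_under")
  )
  data.frame(
    hist_grade = h, pdff_grade = p,
    discordant = d != 0L, magnitude = abs(d), direction = direction
  )
}

#' Scalar distance from a PDFF value to its closest grade threshold
#'
#' The closeness of a PDFF measurement to the nearest grade cut-point
#' (5.75, 15.5 or 21.35%), used as a candidate predictor of grading
#' discordance: values near a threshold are easily pushed across it by
#' measurement noise. For example, PDFF values of 3% and 18.25% both lie
#' 2.75% from their closest thresholds.
#'
#' @param pdff_pct Numeric vector of PDFF values in percent, non-negative.
#' @return Numeric vector of non-negative distances (percent).
#' @examples
#' pdff_distance_to_threshold(c(3, 18.25, 5.75))
#' @export
pdff_distance_to_threshold <- function(pdff_pct) {
  if (!is.numeric(pdff_pct) || anyNA(pdff_pct)) {
    stop("'pdff_pct' must be numeric without NA")
  }
  if (any(pdff_pct < 0)) stop("PDFF must be non-negative")
  apply(abs(outer(pdff_pct, PDFF_GRADE_THRESHOLDS, "-")), 1L, min)
}

#' Append grading and discordance columns to a cohort table
#'
#' Convenience wrapper used by the pipeline: derives the PDFF grade from
#' \code{pdff_pct}, the discordance constructs against \code{hist_grade}, and
#' the distance-to-threshold feature.
#'
#' @param cohort A cohort data.frame with at least \code{pdff_pct} and
#'   \code{hist_grade} columns (see \code{\link{generate_cohort}}).
#' @return The cohort with columns \code{pdff_grade}, \code{discordant},
#'   \code{magnitude}, \code{direction}, \code{pdff_distance} appended.
#' @export
grade_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("pdff_pct", "hist_grade") %in% names(cohort)))
  cohort$pdff_grade <- grade_pdff(cohort$pdff_pct)
  dc <- assess_discordance(cohort$hist_grade, cohort$pdff_grade)
  cohort$discordant <- dc$discordant
  cohort$magnitude <- dc$magnitude
  cohort$direction <- dc$direction
  cohort$pdff_distance <- pdff_distance_to_threshold(cohort$pdff_pct)
  cohort
}
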