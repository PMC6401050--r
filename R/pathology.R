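#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between two vectors (typically the six
#' monitor-point pressures and the six averaged Smith scores of one standoff
#' and lung side). Constant input is an error, not a zero: an undefined
#' correlation must not silently enter the validation report.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input vector")
  stats::cor(x, y)
}

#' Two-tailed p-value of a Pearson correlation
#'
#' Exact small-sample test via the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' A perfect fit (`|r| = 1`) returns 0 flagged with attribute
#' `exact_fit = TRUE`.
#'
#' @param r Correlation coefficient.
#' @param n Number of paired observations, >= 3.
#' @return Two-tailed p-value.
#' @examples
#' pearson_pvalue(0.899, 6)  # ~0.015
#' @export
pearson_pvalue <- function(r, n) {
  stopifnot(length(r) == 1L, length(n) == 1L, n >= 3)
  if (abs(r) > 1) stop("|r| cannot exceed 1")
  if (abs(r) == 1) return(structure(0, exact_fit = TRUE))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Paired t-test between injured and untreated scores
#'
#' Classical paired t-test on the point-wise differences (df = n - 1;
#' n = 6 monitor points in the study design), two-tailed.
#'
#' @param injured,untreated Numeric vectors of equal length >= 2.
#' @return List with elements `t` and `p`.
#' @export
paired_t <- function(injured, untreated) {
  if (length(injured) != length(untreated)) stop("vectors must have equal length")
  if (length(injured) < 2L) stop("need at least 2 pairs")
  if (stats::sd(injured - untreated) == 0)
    stop("zero-variance differences: paired t statistic undefined")
  tt <- stats::t.test(injured, untreated, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Total Smith score
#'
#' Sums the edema, hemorrhage and inflammation components (each graded 0-4,
#' fractional values allowed for scores averaged over pathologists) into the
#' 0-12 total.
#'
#' @param edema,hemorrhage,inflammation Component scores in \[0, 4\]
#'   (vectorised).
#' @return Total score in \[0, 12\].
#' @export
smith_total <- function(edema, hemorrhage, inflammation) {
  comp <- cbind(edema, hemorrhage, inflammation)
  if (any(comp < 0 | comp > 4))
    stop("Smith components must lie in [0, 4]")
  as.numeric(edema + hemorrhage + inflammation)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "blastrat")
  if (p == "") p <- file.path("inst", "extdata", file) # pre-install fallback
  if (!file.exists(p)) stop("fixture not found: ", file)
  p
}

#' Packaged lung monitor-point pressure table
#'
#' Simulated lung-surface pressures (Pa) at the six monitor points, both lung
#' sides, five standoffs, as transcribed from the study's monitor table. The
#' fixture file carries a verification annotation per row (the Pearson r that
#' the transcription reproduces).
#'
#' @return Data frame with columns `group` ("40".."80", the standoff in cm),
#'   `side` ("L"/"R"), `point_name`, `pressure_pa`.
#' @export
load_lung_pressures <- function() {
  utils::read.csv(fixture_path("lung_monitor_pressures.csv"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged Smith pathology score table
#'
#' Averaged total Smith scores (0-12) at the six biopsy points, both lung
#' sides, for the five injured groups and the untreated group.
#'
#' @return Data frame with columns `group` ("40".."80" or "untreated"),
#'   `side`, `point_name`, `score`.
#' @export
load_smith_scores <- function() {
  utils::read.csv(fixture_path("smith_scores.csv"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Validation report: pressure vs pathology
#'
#' For every (standoff, side) pairs the six monitor-point pressures with the
#' six averaged Smith scores and reports the Pearson correlation, its
#' two-tailed p-value, and the paired t-test p-value of the scores against
#' the same side's untreated scores. Values are kept at full precision; the
#' print method rounds to 3 decimals, matching the convention of the
#' original report.
#'
#' @param pressures Pressure table as from [load_lung_pressures()] (columns
#'   `group`, `side`, `point_name`, `pressure_pa`).
#' @param scores Score table as from [load_smith_scores()] (columns `group`,
#'   `side`, `point_name`, `score`), containing an `untreated` group.
#' @param strong_r Threshold above which a correlation is flagged strong
#'   (default 0.8).
#' @return Data frame of class `validation_report` with one row per
#'   (standoff, side): `group`, `side`, `pearson_r`, `pearson_p`,
#'   `paired_t_p`, `strong`.
#' @export
validation_report <- function(pressures, scores, strong_r = 0.8) {
  need <- monitor_point_names
  groups <- unique(pressures$group)
  out <- NULL
  for (g in as.character(groups)) {
    for (side in c("L", "R")) {
      p <- pressures[pressures$group == g & pressures$side == side, ]
      s <- scores[scores$group == g & scores$side == side, ]
      u <- scores[scores$group == "untreated" & scores$side == side, ]
      for (tab in list(p = p, s = s, u = u)) {
        miss <- setdiff(need, tab$point_name)
        if (length(miss) > 0L)
          stop("missing monitor point(s) for (", g, ", ", side, "): ",
               paste(miss, collapse = ", "))
      }
      pv <- p$pressure_pa[match(need, p$point_name)]
      sv <- s$score[match(need, s$point_name)]
      uv <- u$score[match(need, u$point_name)]
      r <- pearson(pv, sv)
      out <- rbind(out, data.frame(
        group = g, side = side,
        pearson_r = r,
        pearson_p = as.numeric(pearson_pvalue(r, length(pv))),
        paired_t_p = paired_t(sv, uv)$p,
        strong = abs(r) >= strong_r))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  y <- as.data.frame(x)
  y$pearson_r <- round(y$pearson_r, 3)
  y$pearson_p <- round(y$pearson_p, 3)
  y$paired_t_p <- round(y$paired_t_p, 3)
  cat("Validation report (Pearson r over 6 monitor points; paired t vs untreated)\n")
  print(y, row.names = FALSE)
  invisible(x)
}
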