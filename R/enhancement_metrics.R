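#' Per-patient contrast enhancement
#'
#' Computes each patient's contrast enhancement in Hounsfield units:
#' aortic enhancement is the hepatic-arterial-phase CT number minus the
#' unenhanced CT number, and hepatic enhancement is the mean of the right
#' and left lobe portal-venous-phase CT numbers minus the mean of the two
#' unenhanced lobe values (equal-weight lobe average; with equal weights
#' the averaging and subtraction orders commute).
#'
#' Non-positive enhancement is physiologically anomalous; such rows are
#' flagged, not dropped, so descriptive statistics still see them while the
#' dose transform downstream can exclude them explicitly.
#'
#' @param cohort Cohort `data.frame` (see [generate_cohort()]); the six HU
#'   columns must be present and finite.
#' @return A `data.frame` with columns `patient_id`, `protocol_kvp`,
#'   `aorta_enh_hu`, `liver_enh_hu`, and logical flags `aorta_nonpositive`,
#'   `liver_nonpositive`.
#' @examples
#' rec <- data.frame(patient_id = "p1", protocol_kvp = 120,
#'                   aorta_unenh_hu = 40, aorta_hap_hu = 380,
#'                   liver_r_unenh_hu = 55, liver_l_unenh_hu = 57,
#'                   liver_r_pvp_hu = 110, liver_l_pvp_hu = 116)
#' compute_enhancement(rec)  # aorta 340 HU, liver 57 HU
#' @export
compute_enhancement <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("cohort must be a non-empty data.frame", call. = FALSE)
  hu_cols <- c("aorta_unenh_hu", "aorta_hap_hu", "liver_r_unenh_hu",
               "liver_l_unenh_hu", "liver_r_pvp_hu", "liver_l_pvp_hu")
  for (col in hu_cols) {
    if (is.null(cohort[[col]]))
      stop("measurement error: missing field '", col, "'", call. = FALSE)
    if (any(!is.finite(cohort[[col]])))
      stop("measurement error: non-finite value in field '", col, "'", call. = FALSE)
  }
  aorta_enh <- cohort$aorta_hap_hu - cohort$aorta_unenh_hu
  liver_enh <- (cohort$liver_r_pvp_hu + cohort$liver_l_pvp_hu) / 2 -
    (cohort$liver_r_unenh_hu + cohort$liver_l_unenh_hu) / 2
  data.frame(
    patient_id = cohort$patient_id,
    protocol_kvp = cohort$protocol_kvp,
    aorta_enh_hu = aorta_enh,
    liver_enh_hu = liver_enh,
    aorta_nonpositive = aorta_enh <= 0,
    liver_nonpositive = liver_enh <= 0,
    stringsAsFactors = FALSE
  )
}

#' Write per-patient enhancement values to CSV
#'
#' @param enhancement Result of [compute_enhancement()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_enhancement_csv <- function(enhancement, path) {
  cols <- c("patient_id", "protocol_kvp", "aorta_enh_hu", "liver_enh_hu")
  out <- enhancement[, cols]
  for (col in cols) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Diagnostic-threshold attainment rate
#'
#' Counts how many enhancement values strictly exceed a diagnostic
#' threshold (e.g. >280 HU for the aorta at HAP, >50 HU for hepatic
#' parenchyma at PVP) and returns the empirical attainment proportion.
#'
#' @param enhancements Numeric vector of enhancement values (HU), non-empty
#'   and finite.
#' @param threshold Diagnostic threshold (HU); attainment is strict (`>`).
#' @return An object of class `attainment_rate`: list with `k` (count above
#'   threshold), `n` (sample size), `rate` (`k/n`) and `threshold`.
#' @examples
#' attainment_rate(c(300, 250, 290), 280)  # 2/3
#' @export
attainment_rate <- function(enhancements, threshold) {
  if (length(enhancements) == 0)
    stop("attainment_rate() requires a non-empty sample", call. = FALSE)
  if (any(!is.finite(enhancements)))
    stop("attainment_rate() requires finite values", call. = FALSE)
  k <- sum(enhancements > threshold)
  out <- list(k = k, n = length(enhancements), rate = k / length(enhancements),
              threshold = threshold)
  class(out) <- "attainment_rate"
  out
}

#' @export
print.attainment_rate <- function(x, ...) {
  cat(sprintf("Attainment: %d/%d (%.1f%%) above %g HU\n",
              x$k, x$n, 100 * x$rate, x$threshold))
  invisible(x)
}

#' Two-sample t test between protocol arms
#'
#' Pooled-variance Student t test by default; set `pooled = FALSE` for the
#' Welch variant. Two-sided.
#'
#' @param group_a,group_b Numeric vectors, each of size >= 2.
#' @param pooled Use the pooled-variance (classical Student) statistic?
#' @return A `comparison_result`: list with `statistic`,
#'   `degrees_of_freedom`, `p_value`, `test_name`.
#' @export
two_sample_t <- function(group_a, group_b, pooled = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least two observations", call. = FALSE)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop("both groups have zero variance; t statistic undefined", call. = FALSE)
  ht <- stats::t.test(group_a, group_b, var.equal = isTRUE(pooled))
  out <- list(
    statistic = unname(ht$statistic),
    degrees_of_freedom = unname(ht$parameter),
    p_value = ht$p.value,
    test_name = if (isTRUE(pooled)) "Student t (pooled variance)" else "Welch t"
  )
  class(out) <- "comparison_result"
  out
}

#' Chi-square test for a 2x2 sex-ratio table
#'
#' Pearson chi-square with 1 degree of freedom, without Yates continuity
#' correction by default (immaterial at the study's group sizes; set
#' `correct = TRUE` to apply it).
#'
#' @param counts_a,counts_b Length-2 non-negative integer vectors
#'   (male, female) for the two arms.
#' @param correct Apply the continuity correction?
#' @return A `comparison_result`.
#' @export
chi_square_2x2 <- function(counts_a, counts_b, correct = FALSE) {
  if (length(counts_a) != 2 || length(counts_b) != 2)
    stop("counts must be length-2 (male, female) vectors", call. = FALSE)
  tab <- rbind(counts_a, counts_b)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: every row and column total must be positive", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = isTRUE(correct)))
  out <- list(
    statistic = unname(ht$statistic),
    degrees_of_freedom = unname(ht$parameter),
    p_value = ht$p.value,
    test_name = if (isTRUE(correct)) "Pearson chi-square (Yates)" else "Pearson chi-square"
  )
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}
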