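#' Contrast volume required to reach a diagnostic threshold
#'
#' Converts an observed enhancement into the contrast volume per kilogram
#' that would have brought that patient exactly to the diagnostic threshold,
#' assuming enhancement proportional to iodine dose per kg at fixed
#' injection duration:
#' `required = administered_volume * threshold / enhancement`.
#' The identity `required * enhancement = administered * threshold` holds
#' exactly for every returned value.
#'
#' Enhancement at or below the positivity floor (default `threshold / 10`)
#' would make the reciprocal explode; such values return `NA` with a warning
#' listing their positions. [transform_cohort()] turns those `NA`s into an
#' explicit exclusion record.
#'
#' @param enhancement Observed enhancement(s), HU.
#' @param threshold Diagnostic threshold, HU (> 0); 280 for aorta, 50 for
#'   hepatic parenchyma.
#' @param administered_volume Administered contrast, mL/kg (> 0).
#' @param floor Positivity floor below which a value is excluded.
#' @return Numeric vector of required volumes (mL/kg), `NA` where excluded.
#' @examples
#' required_volume(280, 280, 2.0)   # exactly at threshold -> 2.0
#' required_volume(560, 280, 2.0)   # double enhancement -> 1.0
#' @export
required_volume <- function(enhancement, threshold, administered_volume = 2.0,
                            floor = threshold / 10) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive", call. = FALSE)
  if (!is.finite(administered_volume) || administered_volume <= 0)
    stop("administered_volume must be positive", call. = FALSE)
  if (any(!is.finite(enhancement)))
    stop("enhancement values must be finite", call. = FALSE)
  v <- administered_volume * threshold / enhancement
  excluded <- enhancement <= floor
  if (any(excluded)) {
    v[excluded] <- NA_real_
    warning(sprintf("%d enhancement value(s) at or below the floor (%g HU) excluded",
                    sum(excluded), floor), call. = FALSE)
  }
  v
}

site_threshold <- function(site) switch(site, aorta = 280, liver = 50)

#' Required-volume transform over a cohort
#'
#' Applies [required_volume()] to every patient's enhancement at the chosen
#' target site, keeping exclusions explicit: excluded patients are reported
#' in the `excluded` attribute (and a message) rather than silently dropped.
#'
#' @param enhancement Result of [compute_enhancement()].
#' @param site `"aorta"` (HAP, threshold 280 HU) or `"liver"` (PVP,
#'   threshold 50 HU).
#' @param administered_volume Administered contrast, mL/kg.
#' @param threshold Override the site's default threshold (HU).
#' @param quiet Suppress the exclusion message.
#' @return A `data.frame` with columns `patient_id`, `protocol_kvp`, `site`,
#'   `threshold_hu`, `administered_ml_per_kg`, `required_ml_per_kg`; the
#'   attribute `excluded` holds the patient ids removed at the positivity
#'   floor.
#' @export
transform_cohort <- function(enhancement, site = c("aorta", "liver"),
                             administered_volume = 2.0, threshold = NULL,
                             quiet = FALSE) {
  site <- match.arg(site)
  if (!is.data.frame(enhancement) || nrow(enhancement) == 0)
    stop("enhancement must be a non-empty data.frame", call. = FALSE)
  threshold <- threshold %||% site_threshold(site)
  enh <- if (site == "aorta") enhancement$aorta_enh_hu else enhancement$liver_enh_hu
  if (is.null(enh))
    stop("enhancement is missing the '", site, "' column", call. = FALSE)
  v <- suppressWarnings(
    required_volume(enh, threshold, administered_volume)
  )
  keep <- !is.na(v)
  excluded_ids <- enhancement$patient_id[!keep]
  if (length(excluded_ids) > 0 && !isTRUE(quiet))
    message(sprintf("excluded %d patient(s) below the enhancement floor: %s",
                    length(excluded_ids), paste(excluded_ids, collapse = ", ")))
  if (!any(keep))
    stop("all patients excluded at the enhancement floor; nothing to transform",
         call. = FALSE)
  out <- data.frame(
    patient_id = enhancement$patient_id[keep],
    protocol_kvp = enhancement$protocol_kvp[keep],
    site = site,
    threshold_hu = threshold,
    administered_ml_per_kg = administered_volume,
    required_ml_per_kg = v[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excluded_ids
  out
}

#' Write required-volume samples to CSV
#'
#' @param volumes Result of [transform_cohort()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_volumes_csv <- function(volumes, path) {
  cols <- c("patient_id", "protocol_kvp", "site", "required_ml_per_kg")
  out <- volumes[, cols]
  out$required_ml_per_kg <- sprintf("%.17g", out$required_ml_per_kg)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
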