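# PSA derivative calculators.
#
# All derivatives are carried at full precision; rounding to reporting
# precision happens only in the report layer (see format_cutoff_table).

#' Body mass index and WHO category
#'
#' BMI = weight / height^2 (kg/m^2), categorised with the WHO bins:
#' underweight below 18.5, normal [18.5, 25), overweight [25, 30), obese 30
#' and above.  The category boundaries are inclusive on the upper bin (a BMI
#' of exactly 25 is overweight, exactly 30 is obese).
#'
#' @param weight body weight in kilograms (> 0).
#' @param height body height in meters (> 0).
#' @return list with numeric \code{bmi} and factor \code{category} with
#'   levels UNDERWEIGHT, NORMAL, OVERWEIGHT, OBESE.
#' @examples
#' compute_bmi(80, 1.75)   # 26.1, OVERWEIGHT
#' @export
compute_bmi <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  bmi <- weight / height^2
  list(bmi = bmi, category = bmi_category(bmi))
}

#' @rdname compute_bmi
#' @param bmi body mass index in kg/m^2.
#' @export
bmi_category <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("UNDERWEIGHT", "NORMAL", "OVERWEIGHT", "OBESE"))
}

#' Body surface area, plasma volume and PSA mass
#'
#' \code{compute_bsa} evaluates the body-surface-area formula
#' 0.007184 x weight(kg)^0.425 x height(m)^0.72 (the default,
#' \code{mode = "meters"}: height in meters with exponent 0.72, the
#' convention under which the published PSA-mass scale in micrograms and the
#' published PSAMD cutoffs apply).  \code{mode = "dubois-cm"} instead
#' evaluates the classic Du Bois formula 0.007184 x weight^0.425 x
#' height(cm)^0.725, which returns conventional m^2 values roughly 27x
#' larger; published PSAMD cutoffs do NOT apply on that scale.
#'
#' Plasma volume is BSA x 1.67, and PSA mass (PSAM, micrograms on the
#' meters-convention scale) is serum PSA (ng/mL) x plasma volume.
#'
#' @param weight kilograms (> 0).
#' @param height meters (> 0) in both modes; \code{dubois-cm} converts
#'   internally.
#' @param mode "meters" (default) or "dubois-cm".
#' @return numeric vector.
#' @examples
#' bsa <- compute_bsa(80, 1.75)          # 0.0692
#' pv  <- compute_plasma_volume(bsa)     # 0.1156
#' compute_psa_mass(4.4, pv)             # 0.509 ug
#' @export
compute_bsa <- function(weight, height, mode = c("meters", "dubois-cm")) {
  mode <- match.arg(mode)
  check_positive(weight, "weight")
  check_positive(height, "height")
  if (mode == "meters") {
    0.007184 * weight^0.425 * height^0.72
  } else {
    0.007184 * weight^0.425 * (height * 100)^0.725
  }
}

#' @rdname compute_bsa
#' @param bsa body surface area from \code{compute_bsa} (> 0).
#' @export
compute_plasma_volume <- function(bsa) {
  check_positive(bsa, "bsa")
  1.67 * bsa
}

#' @rdname compute_bsa
#' @param psa serum PSA in ng/mL (>= 0).
#' @param plasma_volume from \code{compute_plasma_volume} (> 0).
#' @export
compute_psa_mass <- function(psa, plasma_volume) {
  check_nonnegative(psa, "psa")
  check_positive(plasma_volume, "plasma_volume")
  psa * plasma_volume
}

#' PSA density and PSA mass density
#'
#' PSAD = serum PSA / prostate weight without seminal vesicles (ng/mL per
#' gram); PSAMD = PSA mass / prostate weight (micrograms per gram).
#'
#' @param psa serum PSA in ng/mL (>= 0).
#' @param psam PSA mass in micrograms (>= 0).
#' @param prostate_weight grams without seminal vesicles (> 0).
#' @return numeric vector.
#' @examples
#' compute_psad(4.4, 44.9)    # 0.098
#' compute_psamd(0.53, 44.9)  # 0.0118
#' @export
compute_psad <- function(psa, prostate_weight) {
  check_nonnegative(psa, "psa")
  check_positive(prostate_weight, "prostate_weight")
  psa / prostate_weight
}

#' @rdname compute_psad
#' @export
compute_psamd <- function(psam, prostate_weight) {
  check_nonnegative(psam, "psam")
  check_positive(prostate_weight, "prostate_weight")
  psam / prostate_weight
}

#' Tumor volume from histologic grid counts and the significance flag
#'
#' Tumor volume is reconstructed from the total mm^2 of tumor counted on
#' 1-mm^2 gridded slide photocopies: mm^2 x section thickness (3 mm) x
#' fixation shrinkage factor (1.12), reported in cm^3.  A tumor volume of
#' 0.5 cm^3 or more (inclusive) is classified as significant disease.
#'
#' @param grid_mm2 total counted tumor area in mm^2 (>= 0).
#' @param thickness_mm tissue section thickness in mm (default 3).
#' @param shrinkage fixation shrinkage factor (default 1.12).
#' @return \code{compute_tumor_volume}: volume in cm^3;
#'   \code{classify_significant}: logical.
#' @examples
#' compute_tumor_volume(100)        # 0.336 cm^3
#' classify_significant(0.5)        # TRUE (threshold inclusive)
#' @export
compute_tumor_volume <- function(grid_mm2, thickness_mm = 3,
                                 shrinkage = 1.12) {
  check_nonnegative(grid_mm2, "grid_mm2")
  grid_mm2 * thickness_mm * shrinkage / 1000
}

#' @rdname compute_tumor_volume
#' @param tv tumor volume in cm^3 (>= 0).
#' @param threshold significance threshold in cm^3 (default 0.5).
#' @export
classify_significant <- function(tv, threshold = 0.5) {
  check_nonnegative(tv, "tv")
  tv >= threshold
}

#' Compute all PSA derivatives for a cohort
#'
#' Augments a cohort with every derived measure: \code{bmi},
#' \code{bmi_category}, \code{bsa}, \code{plasma_volume}, \code{psad},
#' \code{psam}, \code{psamd}, \code{tumor_volume} (from grid counts when the
#' volume itself is absent) and the logical \code{significant} flag.
#' Records missing height or weight get NA for the BMI- and body-size-
#' dependent fields (\code{bmi}, \code{bsa}, \code{plasma_volume},
#' \code{psam}, \code{psamd}) but keep PSAD and tumor volume; the number of
#' such records is attached as \code{attr(x, "n_missing_body_size")}.
#'
#' @param cohort a \code{psa_cohort} (or compatible data.frame).
#' @param bsa_mode "meters" (default) or "dubois-cm"; see
#'   \code{\link{compute_bsa}}.
#' @param tv_threshold significance threshold in cm^3 (default 0.5).
#' @return the cohort with derivative columns appended (class
#'   \code{psa_cohort} preserved).
#' @examples
#' cohort <- generate_cohort(cohort_preset("table1_default", seed = 1))
#' d <- derive_all(cohort)
#' median(d$psad)
#' @export
derive_all <- function(cohort, bsa_mode = c("meters", "dubois-cm"),
                       tv_threshold = 0.5) {
  bsa_mode <- match.arg(bsa_mode)
  x <- as.data.frame(cohort)
  has_body <- !is.na(x$height) & !is.na(x$weight)

  x$bmi <- ifelse(has_body, x$weight / x$height^2, NA_real_)
  x$bmi_category <- bmi_category(x$bmi)
  x$bsa <- NA_real_
  x$bsa[has_body] <- compute_bsa(x$weight[has_body], x$height[has_body],
                                 mode = bsa_mode)
  x$plasma_volume <- ifelse(is.na(x$bsa), NA_real_, 1.67 * x$bsa)
  x$psad <- compute_psad(x$psa, x$prostate_weight)
  x$psam <- x$psa * x$plasma_volume
  x$psamd <- x$psam / x$prostate_weight

  fill_tv <- is.na(x$tumor_volume) & !is.na(x$tumor_grid_mm2)
  x$tumor_volume[fill_tv] <- compute_tumor_volume(x$tumor_grid_mm2[fill_tv])
  x$significant <- x$tumor_volume >= tv_threshold

  attr(x, "n_missing_body_size") <- sum(!has_body)
  attr(x, "bsa_mode") <- bsa_mode
  attr(x, "provenance") <- attr(cohort, "provenance")
  class(x) <- c("psa_cohort", "data.frame")
  x
}

check_positive <- function(x, name) {
  if (any(!is.na(x) & x <= 0)) stop(name, " must be > 0")
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (any(!is.na(x) & x < 0)) stop(name, " must be >= 0")
  invisible(x)
}
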