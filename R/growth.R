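#' Growth reference tables and head-size phenotyping
#'
#' Head circumference, height and cerebral-volume/height reference standards
#' are stored as sex- and age-indexed mean/SD tables. Measurements are
#' converted to z-scores by linear interpolation of the reference mean and SD
#' in age within sex, and to percentiles under a normal assumption. The
#' macrocephaly call uses a permissive cutoff of head circumference more than
#' `threshold_sd` (default 1.5) standard deviations above the age- and
#' sex-matched mean; macrocephalic probands are then partitioned into three
#' subtypes: somatic overgrowth (SO; head circumference and height percentiles
#' both above 90), disproportionate macrocephaly (DMac; height percentile over
#' head-circumference percentile below 0.7) and relative macrocephaly (RM;
#' that ratio at or above 0.7).
#'
#' @name growth_phenotype
NULL

#' Construct a growth reference table
#'
#' @param measure One of `"head_circumference_cm"`, `"height_cm"`,
#'   `"cv_height_ratio"`.
#' @param data A data.frame with columns `sex` (`"M"`/`"F"`), `age_months`,
#'   `mean`, `sd`. Rows must be unique on (sex, age_months) with at least two
#'   ages per sex; `sd` must be positive.
#' @return A `growth_reference` object (a data.frame with attributes).
#' @export
growth_reference <- function(measure, data) {
  measure <- match.arg(measure,
    c("head_circumference_cm", "height_cm", "cv_height_ratio"))
  req <- c("sex", "age_months", "mean", "sd")
  if (!all(req %in% names(data)))
    stop2("reference table needs columns: ", paste(req, collapse = ", "))
  data <- data[order(data$sex, data$age_months), req, drop = FALSE]
  if (anyDuplicated(data[c("sex", "age_months")]))
    stop2("reference rows must be unique on (sex, age_months)")
  if (any(data$sd <= 0) || any(data$mean <= 0))
    stop2("reference mean and sd must be positive")
  if (any(table(data$sex) < 2))
    stop2("need at least two tabulated ages per sex")
  structure(data, class = c("growth_reference", "data.frame"),
            measure = measure)
}

#' Read a growth reference TSV
#'
#' Expects columns `measure`, `sex`, `age_months`, `mean`, `sd`; rows are
#' subset to `measure`.
#'
#' @param path TSV path.
#' @param measure Measure to extract.
#' @return A `growth_reference`.
#' @export
read_growth_reference <- function(path, measure) {
  tab <- read_tsv_file(path)
  if ("measure" %in% names(tab)) tab <- tab[tab$measure == measure, ]
  if (nrow(tab) == 0) stop2("no rows for measure '", measure, "' in ", path)
  growth_reference(measure, tab)
}

# interpolate reference mean and sd at (sex, age); ages outside the tabulated
# range by <= clamp_months are clamped to the nearest row, otherwise error
ref_interp <- function(table, sex, age_months, clamp_months = 3) {
  out <- matrix(NA_real_, length(sex), 2, dimnames = list(NULL, c("mean", "sd")))
  for (s in unique(sex)) {
    sub <- table[table$sex == s, ]
    if (nrow(sub) == 0)
      stop2("sex '", s, "' absent from reference table")
    idx <- which(sex == s)
    age <- age_months[idx]
    lo <- min(sub$age_months); hi <- max(sub$age_months)
    if (any(age < lo - clamp_months | age > hi + clamp_months))
      stop2("age outside reference range (", lo, "-", hi,
            " months) beyond the ", clamp_months, "-month clamp tolerance")
    age <- pmin(pmax(age, lo), hi)
    out[idx, "mean"] <- approx(sub$age_months, sub$mean, xout = age)$y
    out[idx, "sd"]   <- approx(sub$age_months, sub$sd,   xout = age)$y
  }
  out
}

#' Age- and sex-referenced z-score
#'
#' `(value - mean) / sd` with the reference mean and SD linearly interpolated
#' in age within sex. Vectorized over `value`, `sex` and `age_months`.
#'
#' @param value Measurement(s), positive.
#' @param sex `"M"` or `"F"`, recycled against `value`.
#' @param age_months Age(s) in months.
#' @param table A [growth_reference()].
#' @param clamp_months Ages outside the tabulated range by at most this many
#'   months are clamped to the nearest tabulated age; beyond it is an error.
#' @return Numeric vector of z-scores.
#' @export
growth_zscore <- function(value, sex, age_months, table, clamp_months = 3) {
  if (any(value <= 0, na.rm = TRUE)) stop2("measurements must be positive")
  n <- max(length(value), length(sex), length(age_months))
  value <- rep_len(value, n); sex <- rep_len(sex, n)
  age_months <- rep_len(age_months, n)
  ms <- ref_interp(table, sex, age_months, clamp_months)
  unname((value - ms[, "mean"]) / ms[, "sd"])
}

#' Convert z-scores to percentiles and back
#'
#' `percentile_from_z()` returns `100 * pnorm(z)`; `z_from_percentile()` is
#' its inverse. Percentiles are used for the subtype rules (somatic overgrowth
#' and the height/head percentile ratio) while the SD rule drives the
#' macrocephaly call itself.
#'
#' @param z Numeric z-score(s).
#' @return Percentile(s) in (0, 100).
#' @export
percentile_from_z <- function(z) {
  stopifnot(all(is.finite(z)))
  100 * pnorm(z)
}

#' @rdname percentile_from_z
#' @param p Percentile(s) in (0, 100).
#' @export
z_from_percentile <- function(p) {
  stopifnot(all(p > 0 & p < 100))
  qnorm(p / 100)
}

#' Call macrocephaly and its subtypes for a cohort
#'
#' For each proband with head circumference and height present, computes
#' age/sex z-scores and percentiles against the two references, calls
#' macrocephaly when the head-circumference z-score strictly exceeds
#' `threshold_sd`, and assigns exactly one subtype to each macrocephalic
#' proband: SO when both percentiles strictly exceed `so_percentile`
#' (evaluated first so the classes partition), otherwise DMac when
#' height-percentile / head-percentile is strictly below `ratio_cutoff`, RM
#' otherwise (the ratio-equal boundary falls to RM as the complement class).
#' Probands missing a needed measurement are returned with `NA` subtype
#' fields and collected in the `warnings` attribute.
#'
#' @param anthro A data.frame with columns `proband_id`, `sex`, `age_months`,
#'   `head_circumference_cm`, `height_cm` (possibly `NA`).
#' @param hc_table,ht_table [growth_reference()] tables for head
#'   circumference and height.
#' @param threshold_sd Macrocephaly cutoff in SD units (default 1.5).
#' @param so_percentile Somatic-overgrowth percentile cutoff (default 90).
#' @param ratio_cutoff DMac/RM boundary on height/head percentile ratio
#'   (default 0.7).
#' @return A data.frame with columns `proband_id`, `hc_z`, `hc_percentile`,
#'   `height_percentile`, `ratio`, `macrocephaly`, `subtype`
#'   (`"SO"`,`"DMac"`,`"RM"`,`"none"`), with incomplete probands listed in
#'   `attr(, "warnings")` and the rule constants in `attr(, "rules")`.
#' @export
call_head_size <- function(anthro, hc_table, ht_table, threshold_sd = 1.5,
                           so_percentile = 90, ratio_cutoff = 0.7) {
  req <- c("proband_id", "sex", "age_months", "head_circumference_cm",
           "height_cm")
  if (!all(req %in% names(anthro)))
    stop2("anthro needs columns: ", paste(req, collapse = ", "))
  ok <- !is.na(anthro$head_circumference_cm) & !is.na(anthro$height_cm)
  out <- data.frame(proband_id = anthro$proband_id,
                    hc_z = NA_real_, hc_percentile = NA_real_,
                    height_percentile = NA_real_, ratio = NA_real_,
                    macrocephaly = NA, subtype = NA_character_,
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    a <- anthro[ok, ]
    hc_z <- growth_zscore(a$head_circumference_cm, a$sex, a$age_months, hc_table)
    ht_z <- growth_zscore(a$height_cm, a$sex, a$age_months, ht_table)
    hc_p <- percentile_from_z(hc_z)
    ht_p <- percentile_from_z(ht_z)
    ratio <- ht_p / hc_p
    macro <- hc_z > threshold_sd
    subtype <- rep("none", nrow(a))
    so <- macro & hc_p > so_percentile & ht_p > so_percentile
    dmac <- macro & !so & ratio < ratio_cutoff
    rm_ <- macro & !so & !dmac
    subtype[so] <- "SO"; subtype[dmac] <- "DMac"; subtype[rm_] <- "RM"
    out$hc_z[ok] <- hc_z; out$hc_percentile[ok] <- hc_p
    out$height_percentile[ok] <- ht_p; out$ratio[ok] <- ratio
    out$macrocephaly[ok] <- macro; out$subtype[ok] <- subtype
  }
  if (any(!ok)) {
    warning(sum(!ok), " proband(s) missing head circumference or height; ",
            "returned with NA subtype fields")
  }
  attr(out, "warnings") <- anthro$proband_id[!ok]
  attr(out, "rules") <- list(threshold_sd = threshold_sd,
                             so_percentile = so_percentile,
                             ratio_cutoff = ratio_cutoff,
                             strict_inequalities = TRUE,
                             ratio_boundary_class = "RM")
  out
}

#' Call megalencephaly from cerebral volume and height
#'
#' True when the z-score of cerebral volume / height against the age- and
#' sex-matched reference ratio distribution strictly exceeds `threshold_sd`.
#'
#' @param anthro A data.frame with columns `proband_id`, `sex`, `age_months`,
#'   `cerebral_volume_cm3`, `height_cm`.
#' @param ratio_table [growth_reference()] for measure `cv_height_ratio`.
#' @param threshold_sd Cutoff in SD units (default 1.5).
#' @return Logical vector (NA where a measurement is missing), with the
#'   ratio z-scores in `attr(, "z")`.
#' @export
call_megalencephaly <- function(anthro, ratio_table, threshold_sd = 1.5) {
  ok <- !is.na(anthro$cerebral_volume_cm3) & !is.na(anthro$height_cm)
  z <- rep(NA_real_, nrow(anthro))
  if (any(ok)) {
    a <- anthro[ok, ]
    z[ok] <- growth_zscore(a$cerebral_volume_cm3 / a$height_cm, a$sex,
                           a$age_months, ratio_table)
  }
  res <- z > threshold_sd
  attr(res, "z") <- z
  res
}

#' Flag a value as an expression outlier against a population
#'
#' True when `value` lies strictly more than `threshold` population standard
#' deviations above the population mean (the rule used to flag increased
#' transcript abundance in a duplication carrier relative to other cohort
#' members).
#'
#' @param value Scalar measurement.
#' @param population Numeric vector (length >= 3, non-zero variance).
#' @param threshold SD multiple (default 3).
#' @return Logical scalar; z-score in `attr(, "z")`.
#' @export
zscore_outlier <- function(value, population, threshold = 3) {
  if (length(population) < 3) stop2("population must have >= 3 values")
  s <- sd(population)
  if (s == 0) stop2("population has zero variance")
  z <- (value - mean(population)) / s
  structure(z > threshold, z = z)
}
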