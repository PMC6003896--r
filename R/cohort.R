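## Cohort statistics over per-patient shunt estimates from the different
## imaging methods (planar, SPECT/CT with and without corrections, and
## post-therapy PET/CT).
##
## Method column names: lsf_planar, lsf_spect_noc, lsf_spect_ac,
## lsf_spect_acsc (with the 2-cm exclusion), lsf_spect_noc_noexcl,
## lsf_spect_acsc_noexcl, lsf_pet_acsc, lsf_pet_acsc_noexcl (NA where no
## post-therapy scan was done).

.PATIENT_TABLE_CHECKSUM <- list(n = 40, nPet = 20, total = 993.6)

#' The packaged 40-patient shunt table
#'
#' Per-patient shunt fractions (percent) by method, with and without the
#' 2-cm inferior lung exclusion; 20 patients additionally carry
#' post-therapy PET/CT values. One SPECT AC entry (patient 23, 0.3\%) is
#' transcribed as published but is a suspected typographical inversion with
#' that patient's AC+SC entry (0.7\%); no statistic computed here uses the
#' AC column for that patient.
#'
#' @param validate verify the row count, PET subset size and a value
#'   checksum guarding accidental edits
#' @return data.frame of 40 patient records
#' @export
patientLSFTable <- function(validate = TRUE) {
  path <- system.file("extdata", "table3_lsf.csv", package = "shuntQuant",
                      mustWork = TRUE)
  d <- read.csv(path)
  if (validate) {
    ck <- .PATIENT_TABLE_CHECKSUM
    if (nrow(d) != ck$n || sum(!is.na(d$lsf_pet_acsc)) != ck$nPet ||
        abs(sum(d[, -1], na.rm = TRUE) - ck$total) > 1e-6)
      stop("patient table fixture fails its checksum; it may have been edited")
  }
  d
}

.subsetRecords <- function(records, subset = c("all", "pet_only")) {
  subset <- match.arg(subset)
  if (subset == "pet_only") records <- records[!is.na(records$lsf_pet_acsc), ]
  if (nrow(records) == 0) stop("empty subset")
  records
}

.methodColumn <- function(records, method) {
  col <- if (method %in% names(records)) method else paste0("lsf_", method)
  if (!col %in% names(records)) stop("unknown method: ", method)
  v <- records[[col]]
  if (any(is.na(v))) stop("method ", method, " missing for some records")
  v
}

#' Mean and range of a method's shunt values
#'
#' @param records data.frame as from \code{\link{patientLSFTable}}
#' @param method column name (with or without the \code{lsf_} prefix)
#' @param subset \code{"all"} or \code{"pet_only"} (patients with
#'   post-therapy imaging)
#' @return list: method, n, mean, min, max (percent, unrounded)
#' @export
summarizeLSF <- function(records, method, subset = "all") {
  v <- .methodColumn(.subsetRecords(records, subset), method)
  list(method = method, n = length(v), mean = mean(v),
       min = min(v), max = max(v))
}

#' Paired t test between two methods
#'
#' Computed from the definition: t = mean difference / standard error, with
#' n - 1 degrees of freedom, two-sided.
#'
#' @inheritParams summarizeLSF
#' @param methodA,methodB column names
#' @return list: t, p (two-sided), n, meanDiff
#' @export
pairedT <- function(records, methodA, methodB, subset = "all") {
  r <- .subsetRecords(records, subset)
  d <- .methodColumn(r, methodA) - .methodColumn(r, methodB)
  n <- length(d)
  if (n < 2) stop("paired t needs n >= 2")
  se <- sd(d) / sqrt(n)
  t <- if (se == 0) 0 else mean(d) / se
  list(t = t, p = 2 * pt(-abs(t), n - 1), n = n, meanDiff = mean(d))
}

#' Squared Pearson correlation between two methods
#'
#' @inheritParams pairedT
#' @return r^2
#' @export
pearsonR2 <- function(records, methodA, methodB, subset = "all") {
  r <- .subsetRecords(records, subset)
  a <- .methodColumn(r, methodA); b <- .methodColumn(r, methodB)
  if (length(a) < 3) stop("need n >= 3")
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance")
  cor(a, b)^2
}

#' Mean of per-patient ratios between two methods
#'
#' Note this is the mean of ratios, not the ratio of means (which is also
#' returned, as they differ substantially on skewed shunt distributions).
#'
#' @inheritParams pairedT
#' @param numeratorMethod,denominatorMethod column names
#' @return list: meanOfRatios, ratioOfMeans, n
#' @export
ratioMean <- function(records, numeratorMethod, denominatorMethod,
                      subset = "all") {
  r <- .subsetRecords(records, subset)
  num <- .methodColumn(r, numeratorMethod)
  den <- .methodColumn(r, denominatorMethod)
  if (any(den == 0))
    stop("zero denominator for patient ", r$patient[which(den == 0)[1]])
  list(meanOfRatios = mean(num / den), ratioOfMeans = mean(num) / mean(den),
       n = length(num))
}

#' Maximum absolute difference and count above a threshold
#'
#' @inheritParams pairedT
#' @param thresholdPoints difference threshold in shunt percentage points
#' @return list: maxAbsDiff, countExceeding, n
#' @export
diffStats <- function(records, methodA, methodB, subset = "all",
                      thresholdPoints = 5) {
  r <- .subsetRecords(records, subset)
  d <- abs(.methodColumn(r, methodA) - .methodColumn(r, methodB))
  list(maxAbsDiff = max(d), countExceeding = sum(d > thresholdPoints),
       n = length(d))
}
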