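# Closed-phase respirometry: oxygen-depletion slope estimation with
# r-squared quality control, conversion to mass-specific MO2, allometric
# mass standardisation and maximum metabolic rate extraction.

#' Oxygen depletion slope of a closed respirometry phase
#'
#' Ordinary least-squares regression of dissolved oxygen (mg L^-1) on
#' time. Time is sampled in minutes but the slope is reported per hour,
#' the unit in which metabolic rates are expressed. Because a respiring
#' fish can only deplete oxygen, the slope is returned as a positive
#' consumption magnitude; a rising oxygen trace yields a negative value
#' whose records are rejected by [qc_filter()] as non-physical.
#'
#' @param trace An `o2_trace`.
#' @return List with `slope` (mg L^-1 h^-1, positive = depletion) and
#'   `r2` (squared correlation; `NaN` for a perfectly flat trace).
#' @export
estimate_slope <- function(trace) {
  stopifnot(inherits(trace, "o2_trace"))
  t <- trace$times; o2 <- trace$o2
  if (length(t) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing",
                              call. = FALSE)
  if (stats::var(t) == 0) stop("zero time variance", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, t), o2)
  slope_per_min <- fit$coefficients[[2L]]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((o2 - mean(o2))^2)
  r2 <- if (ss_tot == 0) NaN else 1 - ss_res / ss_tot
  list(slope = -slope_per_min * 60, r2 = r2)
}

#' Mass-specific oxygen consumption from a depletion slope
#'
#' `MO2 = slope * (resp_volume - fish_volume) / mass`, in
#' mg O2 kg^-1 h^-1, where the effective volume is the respirometer
#' volume minus the volume of the fish.
#'
#' @param slope Depletion slope, mg L^-1 h^-1 (positive magnitude).
#' @param trace The `o2_trace` the slope came from (supplies volumes and
#'   mass).
#' @return MO2 in mg O2 kg^-1 h^-1.
#' @export
compute_mo2 <- function(slope, trace) {
  stopifnot(inherits(trace, "o2_trace"))
  eff_vol <- trace$resp_volume - trace$fish_volume
  if (!is.finite(eff_vol) || eff_vol <= 0) {
    stop("effective respirometer volume must be positive", call. = FALSE)
  }
  check_positive(trace$mass, "mass")
  slope * eff_vol / trace$mass
}

#' Standardise MO2 to a 1-kg fish
#'
#' Mass-specific metabolic rate scales with body mass to a power
#' `b - 1` (whole-animal exponent `b`, default 0.75), so the per-kg rate
#' of a fish of mass `m` is adjusted to a 1-kg standard as
#' `MO2_std = MO2 * m^(1 - b)`.
#'
#' @param mo2 Mass-specific metabolic rate, mg O2 kg^-1 h^-1.
#' @param mass Body mass, kg (vectorised with `mo2`).
#' @param exponent Whole-animal mass-scaling exponent (default 0.75).
#' @return Standardised MO2, mg O2 kg^-1 h^-1 at 1 kg.
#' @examples
#' standardize_mass(100, 0.0625)  # 50: 0.0625^0.25 = 0.5
#' @export
standardize_mass <- function(mo2, mass, exponent = 0.75) {
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    stop("`mass` must be positive", call. = FALSE)
  }
  mo2 * mass^(1 - exponent)
}

#' Build a metabolic record for one closed phase
#'
#' Convenience wrapper running slope estimation, MO2 conversion and mass
#' standardisation on one trace.
#'
#' @param trace An `o2_trace`.
#' @param r2_min r-squared QC threshold (strict inequality; default
#'   0.95).
#' @param exponent Mass-scaling exponent passed to [standardize_mass()].
#' @return One-row data frame: `speed`, `slope`, `r2`, `mo2`, `mo2_std`,
#'   `passed_qc`.
#' @export
metabolic_record <- function(trace, r2_min = 0.95, exponent = 0.75) {
  est <- estimate_slope(trace)
  mo2 <- compute_mo2(est$slope, trace)
  data.frame(
    speed = trace$speed,
    slope = est$slope,
    r2 = est$r2,
    mo2 = mo2,
    mo2_std = standardize_mass(mo2, trace$mass, exponent),
    passed_qc = is.finite(est$r2) && est$r2 > r2_min && est$slope >= 0
  )
}

#' Quality-control filter on metabolic records
#'
#' Keeps records whose regression r-squared strictly exceeds `r2_min`
#' and whose slope is a physically sensible depletion (non-negative
#' consumption). Order is preserved and the filter is idempotent.
#'
#' @param records Data frame of metabolic records (one row per closed
#'   phase) with columns `r2` and `slope`.
#' @param r2_min Threshold (default 0.95; a record at exactly the
#'   threshold is dropped).
#' @return The passing subset with `passed_qc = TRUE`.
#' @export
qc_filter <- function(records, r2_min = 0.95) {
  if (nrow(records) == 0L) return(records)
  keep <- is.finite(records$r2) & records$r2 > r2_min & records$slope >= 0
  out <- records[keep, , drop = FALSE]
  out$passed_qc <- rep(TRUE, nrow(out))
  out
}

#' Maximum metabolic rate of one individual's swim test
#'
#' The maximum mass-standardised MO2 among QC-passing closed phases of
#' an incremental-velocity test.
#'
#' @param records Data frame of metabolic records for one individual.
#' @param r2_min QC threshold applied before taking the maximum.
#' @return MMR in mg O2 kg^-1 h^-1.
#' @export
extract_mmr <- function(records, r2_min = 0.95) {
  ok <- qc_filter(records, r2_min)
  if (nrow(ok) == 0L) {
    stop("no QC-passing records; MMR undefined", call. = FALSE)
  }
  max(ok$mo2_std)
}

#' Write a per-individual metabolic table as TSV
#'
#' @param records Metabolic record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metabolic_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
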