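#' Percent-of-control normalization of a bulk readout
#'
#' Implements the standard plate normalization: optional background
#' subtraction using medium-only blank wells, then scaling to 100 times the
#' plate-averaged vehicle-control value. ATP luminescence is conventionally
#' normalized without blank subtraction; MTS absorbance and DNA-dye
#' fluorescence subtract the blank mean first.
#'
#' @param raw raw well values.
#' @param control_raw raw values of the vehicle-control wells (at least 2).
#' @param blank_raw raw values of medium-only blank wells; required when
#'   `subtract_background` is TRUE.
#' @param subtract_background subtract the blank-well mean before
#'   normalizing?
#' @return numeric percent-of-control values, with attribute `background`
#'   (the blank mean used, 0 when none).
#' @examples
#' percent_of_control(c(0.5, 0.9), control_raw = c(0.88, 0.92),
#'                    blank_raw = c(0.1, 0.1), subtract_background = TRUE)
#' @export
percent_of_control <- function(raw, control_raw, blank_raw = NULL,
                               subtract_background = FALSE) {
  if (length(control_raw) < 2) stop("at least 2 control wells are required")
  bg <- 0
  if (subtract_background) {
    if (is.null(blank_raw) || !length(blank_raw))
      stop("blank wells are required when subtract_background = TRUE")
    bg <- mean(blank_raw)
  }
  ctrl <- mean(control_raw) - bg
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("control mean must exceed the background")
  out <- 100 * (raw - bg) / ctrl
  attr(out, "background") <- bg
  out
}

#' Normalize all readouts of a simulated or measured well table
#'
#' Applies [percent_of_control()] per readout to a well table in the layout
#' produced by [simulate_dose_plate()] (`role` column marking `control` /
#' `blank` / `treated` wells). ATP is normalized without background
#' subtraction; MTS and the DNA dye subtract the blank mean; counts need no
#' background.
#'
#' @param wells well table with columns `well`, `role`, `conc_molar` and the
#'   readout columns.
#' @param readouts named logical vector: readout column -> subtract
#'   background?
#' @return long data.frame: `well`, `role`, `conc_molar`, `readout`, `raw`,
#'   `background`, `pct_of_control`.
#' @export
normalize_plate <- function(wells,
                            readouts = c(count_truth = FALSE, atp = FALSE,
                                         mts = TRUE, cyquant = TRUE)) {
  stopifnot(all(c("well", "role", "conc_molar") %in% names(wells)))
  missing <- setdiff(names(readouts), names(wells))
  if (length(missing)) stop("missing readout columns: ",
                            paste(missing, collapse = ", "))
  ctrl <- wells$role == "control"
  blank <- wells$role == "blank"
  if (sum(ctrl) < 2) stop("at least 2 control wells are required")
  keep <- !blank
  out <- lapply(names(readouts), function(rd) {
    v <- percent_of_control(wells[[rd]][keep], wells[[rd]][ctrl],
                            blank_raw = if (readouts[[rd]]) wells[[rd]][blank],
                            subtract_background = readouts[[rd]])
    data.frame(well = wells$well[keep], role = wells$role[keep],
               conc_molar = wells$conc_molar[keep],
               readout = if (rd == "count_truth") "count" else rd,
               raw = wells[[rd]][keep],
               background = attr(v, "background"),
               pct_of_control = as.numeric(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Signal-to-cell-number ratio curve
#'
#' Fold change of the normalized signal-to-count ratio versus concentration:
#' per concentration, the replicate-mean signal percent divided by the
#' replicate-mean count percent. At zero effect the fold change is 1 by
#' construction. Concentrations where the count falls below 1% of control
#' (near-total kill) are dropped as undefined.
#'
#' @param signal data.frame with `conc_molar` and `pct_of_control` for the
#'   proxy readout (treated wells).
#' @param count same layout for the cell-count readout.
#' @param count_floor minimum count percent for a defined ratio.
#' @return data.frame of class `ratio_curve`: `conc_molar`, `logconc`,
#'   `signal_pct`, `count_pct`, `fold_change`.
#' @export
ratio_curve <- function(signal, count, count_floor = 1) {
  sc <- sort(unique(signal$conc_molar))
  cc <- sort(unique(count$conc_molar))
  common <- intersect(sc, cc)
  if (!length(common)) stop("signal and count series share no concentrations")
  s_m <- tapply(signal$pct_of_control, signal$conc_molar, mean)[as.character(common)]
  c_m <- tapply(count$pct_of_control, count$conc_molar, mean)[as.character(common)]
  keep <- c_m >= count_floor
  out <- data.frame(conc_molar = common[keep],
                    logconc = log10(common[keep]),
                    signal_pct = as.numeric(s_m[keep]),
                    count_pct = as.numeric(c_m[keep]),
                    fold_change = as.numeric(s_m[keep] / c_m[keep]))
  class(out) <- c("ratio_curve", "data.frame")
  out
}

#' @export
plot.ratio_curve <- function(x, ...) {
  graphics::plot(x$logconc, x$fold_change, type = "b",
                 xlab = "log10 concentration (M)",
                 ylab = "signal / cell-number fold change", ...)
  graphics::abline(h = 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Total mitochondrial mass dose-response series
#'
#' Multiplies the per-well cell count (percent of control) by the per-well
#' mean per-cell mitochondrial intensity (fold change vs control) and
#' renormalizes the product to percent of the control-well product. The
#' resulting series is a derived dose-response readout suitable for
#' [fit_4pl()].
#'
#' @param count data.frame with `well`, `role`, `conc_molar`,
#'   `pct_of_control` for cell counts.
#' @param mito_fold data.frame with `well` and `mito_fold` (mean per-cell
#'   mitochondrial intensity, fold vs control).
#' @return data.frame: `well`, `role`, `conc_molar`, `pct_of_control` of the
#'   count x mito product.
#' @export
total_mito_mass <- function(count, mito_fold) {
  m <- merge(count, mito_fold, by = "well")
  if (!nrow(m)) stop("count and mitochondrial series share no wells")
  prod <- m$pct_of_control * m$mito_fold
  ctrl <- m$role == "control"
  if (sum(ctrl) < 2) stop("at least 2 control wells are required")
  data.frame(well = m$well, role = m$role, conc_molar = m$conc_molar,
             pct_of_control = 100 * prod / mean(prod[ctrl]),
             stringsAsFactors = FALSE)
}

#' Per-well mitochondrial fold change from a per-cell table
#'
#' Mean per-cell integrated mitochondrial intensity per well, expressed as a
#' fold change relative to the mean over the vehicle-control wells.
#'
#' @param cells per-cell table with `well` and `mito_int`.
#' @param control_wells control well addresses.
#' @return data.frame: `well`, `mito_fold`.
#' @export
mito_fold_per_well <- function(cells, control_wells) {
  m <- tapply(cells$mito_int, cells$well, mean)
  ctrl <- m[names(m) %in% control_wells]
  if (length(ctrl) < 2) stop("at least 2 control wells are required")
  data.frame(well = names(m), mito_fold = as.numeric(m / mean(ctrl)),
             stringsAsFactors = FALSE)
}

#' Censored potency/efficacy value
#'
#' Represents reporting-limit results from failed or boundary fits, e.g. a
#' log EC50 known only to exceed the highest tested concentration
#' (`censored(-4.6, "gt")`) or an Emax below the acceptance span
#' (`censored(20, "lt")`). Comparisons use the bound itself, which is
#' conservative when the censoring direction points away from the reference
#' value.
#'
#' @param bound numeric bound.
#' @param direction `"gt"` (true value above the bound) or `"lt"` (below).
#' @return object of class `censored_value`.
#' @export
censored <- function(bound, direction = c("gt", "lt")) {
  direction <- match.arg(direction)
  structure(list(bound = bound, direction = direction),
            class = "censored_value")
}

#' @export
print.censored_value <- function(x, ...) {
  cat(if (x$direction == "gt") ">" else "<", format(x$bound), "\n")
  invisible(x)
}

cmp_value <- function(x) {
  if (inherits(x, "censored_value")) x$bound else as.numeric(x)
}

# pull log_ec50 / emax / validity out of a logistic4, a censored value, a
# plain number, or a list(log_ec50 =, emax =, valid =)
fit_summary_for_compare <- function(fit, what = c("log_ec50", "emax")) {
  if (inherits(fit, "logistic4")) {
    pot <- derive_potency(fit)
    list(log_ec50 = pot$log_ec50, emax = pot$emax_pct_reduction,
         valid = !isFALSE(fit$valid))
  } else if (is.list(fit) && !inherits(fit, "censored_value")) {
    list(log_ec50 = fit$log_ec50, emax = fit$emax,
         valid = if (is.null(fit$valid)) TRUE else fit$valid)
  } else stop("unsupported fit representation")
}

#' Compare a proxy-assay fit against the cell-count fit
#'
#' Flags assay-format discrepancies using the screening reporting rules: a
#' proxy (ATP/MTS/DNA-dye/mito) log EC50 differing from the cell-count log
#' EC50 by more than 1 log10 unit, or an Emax differing by more than 25
#' percentage points. An invalid proxy fit against a valid count fit raises
#' both flags with reason `"no valid fit"`. Censored entries
#' ([censored()]) are compared at their bound.
#'
#' @param count_fit count-readout fit: a `logistic4` or a list with
#'   `log_ec50`, `emax` (entries may be [censored()]), and optional `valid`.
#' @param proxy_fit same for the proxy readout.
#' @param ec50_threshold,emax_threshold flag thresholds (log10 units /
#'   percentage points).
#' @return one-row data.frame of class `format_comparison`:
#'   `delta_log_ec50` (proxy minus count), `delta_emax` (count minus proxy),
#'   `ec50_flag`, `emax_flag`, `reason`.
#' @examples
#' compare_formats(list(log_ec50 = -6.8, emax = 79),
#'                 list(log_ec50 = -4.5, emax = 80))
#' @export
compare_formats <- function(count_fit, proxy_fit,
                            ec50_threshold = 1, emax_threshold = 25) {
  cs <- fit_summary_for_compare(count_fit)
  ps <- fit_summary_for_compare(proxy_fit)
  if (cs$valid && !ps$valid) {
    out <- data.frame(delta_log_ec50 = NA_real_, delta_emax = NA_real_,
                      ec50_flag = TRUE, emax_flag = TRUE,
                      reason = "no valid fit", stringsAsFactors = FALSE)
  } else if (!cs$valid) {
    out <- data.frame(delta_log_ec50 = NA_real_, delta_emax = NA_real_,
                      ec50_flag = NA, emax_flag = NA,
                      reason = "no valid count fit", stringsAsFactors = FALSE)
  } else {
    d_ec <- cmp_value(ps$log_ec50) - cmp_value(cs$log_ec50)
    d_em <- cmp_value(cs$emax) - cmp_value(ps$emax)
    out <- data.frame(delta_log_ec50 = d_ec, delta_emax = d_em,
                      ec50_flag = abs(d_ec) > ec50_threshold,
                      emax_flag = abs(d_em) > emax_threshold,
                      reason = "", stringsAsFactors = FALSE)
  }
  class(out) <- c("format_comparison", "data.frame")
  out
}
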