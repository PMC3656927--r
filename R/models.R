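#' Compound mechanism-of-action model
#'
#' Describes how a compound reshapes a cell population with concentration.
#' The primary response (potency `primary_logec50`, steepness `primary_hill`)
#' moves the population from the untreated cycling mixture towards
#' `primary_phenotype`. An optional second transition at higher concentration
#' (`switch_logec50`, which must exceed `primary_logec50`) moves it further to
#' `switch_phenotype` and can kill a fraction of the population
#' (`kill_fraction_at_switch`), producing the biphasic dose responses seen with
#' DNA-damaging agents and mitotic kinase inhibitors: cytostatic arrest with
#' cell enlargement at low dose, apoptosis (sub-G1 accumulation) at high dose.
#'
#' @param name compound name.
#' @param primary_logec50 log10 molar potency of the primary response.
#' @param primary_hill Hill coefficient (> 0) of the primary response.
#' @param primary_phenotype [phenotype_mixture()] reached at saturating primary
#'   response.
#' @param switch_logec50 optional log10 molar potency of the secondary
#'   (higher-concentration) transition.
#' @param switch_hill Hill coefficient of the secondary transition.
#' @param switch_phenotype mixture reached at saturating secondary response.
#' @param kill_fraction_at_switch fraction of cells lost at full secondary
#'   response, in `[0, 1]`.
#' @return an object of class `compound_model`.
#' @export
compound_model <- function(name, primary_logec50, primary_hill,
                           primary_phenotype,
                           switch_logec50 = NULL, switch_hill = NULL,
                           switch_phenotype = NULL,
                           kill_fraction_at_switch = 0) {
  stopifnot(is.character(name), primary_hill > 0,
            inherits(primary_phenotype, "phenotype_mixture"))
  if (!is.null(switch_logec50)) {
    if (switch_logec50 <= primary_logec50)
      stop("switch_logec50 must exceed primary_logec50 ",
           "(secondary phenotype occurs at higher concentration)")
    stopifnot(switch_hill > 0, inherits(switch_phenotype, "phenotype_mixture"),
              kill_fraction_at_switch >= 0, kill_fraction_at_switch <= 1)
  }
  structure(list(name = name,
                 primary_logec50 = primary_logec50,
                 primary_hill = primary_hill,
                 primary_phenotype = primary_phenotype,
                 switch_logec50 = switch_logec50,
                 switch_hill = switch_hill,
                 switch_phenotype = switch_phenotype,
                 kill_fraction_at_switch = kill_fraction_at_switch),
            class = "compound_model")
}

#' @export
print.compound_model <- function(x, ...) {
  cat(sprintf("<compound_model %s: primary logEC50 %.2f (hill %.2g)%s>\n",
              x$name, x$primary_logec50, x$primary_hill,
              if (is.null(x$switch_logec50)) "" else
                sprintf(", switch at %.2f (kill %.0f%%)",
                        x$switch_logec50, 100 * x$kill_fraction_at_switch)))
  invisible(x)
}

#' Exponential growth model for a screening well
#'
#' Untreated wells grow exponentially from `seed_count` for `duration` hours
#' with the given doubling time (the default 48 h / 20 h corresponds to
#' roughly 2-3 doublings, the usual design point for proliferation screens).
#' Drug arrest suppresses the net growth via a Hill function whose maximal
#' inhibition `arrest_efficacy_max` sets the lower asymptote of the cell-count
#' dose-response curve.
#'
#' @param doubling_time doubling time, hours.
#' @param seed_count cells seeded per well.
#' @param duration treatment/growth duration, hours.
#' @param arrest_efficacy_max maximal fractional reduction of final cell count,
#'   in `[0, 1]`.
#' @return an object of class `growth_model`.
#' @export
growth_model <- function(doubling_time = 20, seed_count = 750, duration = 48,
                         arrest_efficacy_max = 0.85) {
  stopifnot(doubling_time > 0, seed_count >= 1, duration >= 0,
            arrest_efficacy_max >= 0, arrest_efficacy_max <= 1)
  structure(list(doubling_time = doubling_time, seed_count = seed_count,
                 duration = duration,
                 arrest_efficacy_max = arrest_efficacy_max),
            class = "growth_model")
}

#' Measurement noise model
#'
#' Coefficients of variation of the multiplicative lognormal noise applied to
#' per-cell staining intensity (`dna_cv`), cell area (`area_cv`) and bulk
#' plate-reader signals (`readout_cv`), plus the imaging background level
#' (counts per pixel; Poisson shot noise is applied when positive) and the
#' master RNG seed from which all substreams are derived.
#'
#' @param dna_cv CV of per-cell DNA staining noise (default 0.06, which
#'   reproduces the peak broadening typical of image-derived DNA histograms).
#' @param area_cv CV of per-cell area noise.
#' @param readout_cv CV of bulk readout noise.
#' @param background_level mean image background, counts per pixel.
#' @param rng_seed integer master seed.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(dna_cv = 0.06, area_cv = 0.15, readout_cv = 0.05,
                        background_level = 100, rng_seed = 1L) {
  stopifnot(dna_cv >= 0, area_cv >= 0, readout_cv >= 0, background_level >= 0)
  structure(list(dna_cv = dna_cv, area_cv = area_cv, readout_cv = readout_cv,
                 background_level = background_level,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_model")
}

#' Predefined mechanism-of-action scenarios
#'
#' Ready-made [compound_model()]s reproducing the canonical assay-discrepancy
#' phenotypes:
#' \describe{
#'   \item{`size_doubling_arrest`}{pure cytostatic G2/M arrest with 2-fold cell
#'     enlargement and proportional mitochondrial/ATP increase, no cell death
#'     (taxane-like): ATP and MTS dose-response curves are much shallower than
#'     the cell-count curve, with a ~2-fold per-cell ratio plateau.}
#'   \item{`arrest_then_apoptosis`}{G2 arrest with enlargement at low dose
#'     switching to sub-G1 apoptosis (80% kill) at ~30-fold higher
#'     concentration (topoisomerase-poison-like): right-shifted ATP/MTS curves
#'     converging at high dose, bell-shaped per-cell ratio.}
#'   \item{`s_phase_arrest`}{persistent S-phase arrest with enlargement and no
#'     convergence (nucleoside-analog-like): ATP/MTS Emax far below the count
#'     Emax across the whole range.}
#'   \item{`endoreduplication_switch`}{endoreduplication (8N) at low dose
#'     switching to 4N/sub-G1 death at high dose (Aurora-B-inhibitor-like):
#'     multiphasic proxy readouts.}
#'   \item{`null`}{no effect at any concentration (vehicle-like).}
#' }
#'
#' @param name scenario name (see Details).
#' @return a `compound_model`.
#' @export
hcs_scenario <- function(name = c("size_doubling_arrest", "arrest_then_apoptosis",
                                  "s_phase_arrest", "endoreduplication_switch",
                                  "null")) {
  name <- match.arg(name)
  # G2-arrested cells grow strongly before dying; 5x the G1 area puts the
  # per-cell ATP elevation at its reported 4-5-fold maximum
  big_g2 <- phenotype_mixture(
    list(phenotype_state("G2M", size_multiplier = 5),
         phenotype_state("subG1", size_multiplier = 0.4)),
    c(0.95, 0.05))
  switch(name,
    size_doubling_arrest = compound_model(
      "size_doubling_arrest", primary_logec50 = -8, primary_hill = 1.5,
      # pure mitotic arrest, no cell death; 2.2x the G1 cell area gives a
      # 2-fold per-cell ATP elevation over the untreated population mean
      # (whose mean size multiplier is 1.1)
      primary_phenotype = phenotype_mixture(
        list(phenotype_state("G2M", size_multiplier = 2.2)), 1)),
    arrest_then_apoptosis = compound_model(
      "arrest_then_apoptosis", primary_logec50 = -6.8, primary_hill = 1.2,
      primary_phenotype = big_g2,
      switch_logec50 = -5.3, switch_hill = 1.5,
      switch_phenotype = phenotype_mixture(
        list(phenotype_state("subG1", size_multiplier = 0.4),
             phenotype_state("G2M", size_multiplier = 1.5)),
        c(0.8, 0.2)),
      kill_fraction_at_switch = 0.8),
    s_phase_arrest = compound_model(
      "s_phase_arrest", primary_logec50 = -8.7, primary_hill = 1.2,
      primary_phenotype = phenotype_mixture(
        list(phenotype_state("S", size_multiplier = 2.5),
             phenotype_state("subG1", size_multiplier = 0.4)),
        c(0.92, 0.08))),
    endoreduplication_switch = compound_model(
      "endoreduplication_switch", primary_logec50 = -7.3, primary_hill = 1.2,
      primary_phenotype = phenotype_mixture(
        list(phenotype_state("endoredup", size_multiplier = 2.5)), 1),
      switch_logec50 = -5.8, switch_hill = 1.5,
      switch_phenotype = phenotype_mixture(
        list(phenotype_state("G2M", size_multiplier = 1.5),
             phenotype_state("subG1", size_multiplier = 0.4)),
        c(0.45, 0.55)),
      kill_fraction_at_switch = 0.6),
    null = compound_model("null", primary_logec50 = -6, primary_hill = 1,
                          primary_phenotype = cycling_mixture()))
}
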