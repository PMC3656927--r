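#' Sample a per-cell population from a phenotype mixture
#'
#' Draws `n` cells from a weighted mixture of phenotype states and measures
#' them through the staining-noise model: measured integrated DNA intensity is
#' `reference_scale * dna_content * lognormal(1, dna_cv)`, cell area is
#' `base_area * size_multiplier * lognormal(1, area_cv)`, and mitochondrial /
#' TMRE intensities are `area * mito_per_area` and `area * tmre_per_area`.
#' The lognormal noise factors have mean exactly 1, so expectations are
#' noise-free and the zero-CV case is exact.
#'
#' @param mixture a [phenotype_mixture()].
#' @param n number of cells (>= 0).
#' @param noise a [noise_model()]; `noise$rng_seed` (combined with
#'   `stream`) makes the draw fully reproducible.
#' @param reference_scale integrated DNA intensity of a noise-free 2N cell
#'   (arbitrary instrument units).
#' @param base_area area of an untreated G1 cell, pixels.
#' @param well,plate address metadata copied into the output.
#' @param stream substream counter (wells of a plate use their well index).
#' @return a data.frame with one row per cell: `plate`, `well`, `cell_id`,
#'   `dna_int`, `area`, `mito_int`, `tmre_int`, plus ground-truth columns
#'   `state` and `dna_content`.
#' @examples
#' cells <- sample_population(cycling_mixture(), 500, noise_model(rng_seed = 7))
#' hist(log2(cells$dna_int / 1000), breaks = 50)
#' @export
sample_population <- function(mixture, n, noise = noise_model(),
                              reference_scale = 1000, base_area = 500,
                              well = "A01", plate = "P1", stream = 0L) {
  stopifnot(inherits(mixture, "phenotype_mixture"), inherits(noise, "noise_model"))
  if (length(n) != 1 || is.na(n) || n < 0)
    stop("n must be a single non-negative count")
  n <- as.integer(n)
  empty <- data.frame(plate = character(0), well = character(0),
                      cell_id = integer(0), dna_int = numeric(0),
                      area = numeric(0), mito_int = numeric(0),
                      tmre_int = numeric(0), state = character(0),
                      dna_content = numeric(0), atp_per_size = numeric(0),
                      mts_per_size = numeric(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)

  with_local_seed(substream_seed(noise$rng_seed, stream), {
    idx <- sample.int(length(mixture$states), n, replace = TRUE,
                      prob = mixture$weights)
    dna_content <- numeric(n)
    area <- numeric(n)
    mito <- numeric(n)
    tmre <- numeric(n)
    lab <- character(n)
    atp_c <- numeric(n)
    mts_c <- numeric(n)
    for (k in seq_along(mixture$states)) {
      sel <- which(idx == k)
      if (!length(sel)) next
      st <- mixture$states[[k]]
      lab[sel] <- st$label
      dna_content[sel] <- draw_dna_content(st, length(sel))
      area[sel] <- base_area * st$size_multiplier * rlnorm1(length(sel), noise$area_cv)
      mito[sel] <- area[sel] * st$mito_per_area
      tmre[sel] <- area[sel] * st$tmre_per_area
      atp_c[sel] <- st$atp_per_size
      mts_c[sel] <- st$mts_per_size
    }
    dna_int <- reference_scale * dna_content * rlnorm1(n, noise$dna_cv)
    data.frame(plate = plate, well = well, cell_id = seq_len(n),
               dna_int = dna_int, area = area, mito_int = mito,
               tmre_int = tmre, state = lab, dna_content = dna_content,
               atp_per_size = atp_c, mts_per_size = mts_c,
               stringsAsFactors = FALSE)
  })
}

# Hill response in [0, 1): fraction of maximal effect at log10 concentration x
hill_response <- function(logc, logec50, hill) {
  1 / (1 + 10^(hill * (logec50 - logc)))
}

# dose-dependent phenotype mixture for a compound: linear interpolation, in
# Hill-response space, from the untreated mixture to the primary phenotype and
# then (if present) to the switch phenotype
dose_mixture <- function(compound, untreated, logc) {
  h1 <- hill_response(logc, compound$primary_logec50, compound$primary_hill)
  if (is.null(compound$switch_logec50)) {
    blend_mixtures(list(untreated, compound$primary_phenotype), c(1 - h1, h1))
  } else {
    h2 <- hill_response(logc, compound$switch_logec50, compound$switch_hill)
    treated <- blend_mixtures(list(compound$primary_phenotype,
                                   compound$switch_phenotype),
                              c(1 - h2, h2))
    blend_mixtures(list(untreated, treated), c(1 - h1, h1))
  }
}

# expected final cell count at log10 concentration logc (-Inf for vehicle)
expected_count <- function(compound, growth, logc) {
  n_ctrl <- growth$seed_count * 2^(growth$duration / growth$doubling_time)
  if (!is.finite(logc)) return(n_ctrl)
  h1 <- hill_response(logc, compound$primary_logec50, compound$primary_hill)
  n <- n_ctrl * (1 - growth$arrest_efficacy_max * h1)
  if (!is.null(compound$switch_logec50)) {
    h2 <- hill_response(logc, compound$switch_logec50, compound$switch_hill)
    n <- n * (1 - compound$kill_fraction_at_switch * h2)
  }
  n
}

#' Simulate a dose-response plate
#'
#' Builds a full synthetic screening plate for one compound: vehicle-control
#' wells, blank (medium-only) wells and `wells_per_conc` replicate wells at
#' each concentration. Final per-well cell counts follow exponential growth
#' inhibited by the compound's Hill response (Poisson-sampled around the
#' expectation); the phenotype mixture interpolates from the untreated cycling
#' profile to the compound's primary (and, for biphasic compounds, secondary)
#' phenotype; per-cell records are drawn with [sample_population()].
#'
#' Bulk readouts are computed from the realized cells:
#' ATP `= gain * sum(area * atp_per_size) * lognormal(1, readout_cv)` and MTS
#' analogously with `mts_per_size` (both include every cell, dead or alive,
#' weighted by size); the DNA-dye (CyQuant-like) signal
#' `= gain * sum(dna_content)` over non-sub-G1 cells only, emulating the
#' cell-impermeable quencher that restricts the dye to membrane-intact cells.
#' Blank wells carry background only (MTS/DNA-dye channels).
#'
#' @param compound a [compound_model()].
#' @param growth a [growth_model()].
#' @param concentrations molar concentrations (strictly positive).
#' @param wells_per_conc replicate wells per concentration.
#' @param noise a [noise_model()].
#' @param n_controls number of vehicle (DMSO) control wells (>= 2).
#' @param n_blanks number of medium-only blank wells.
#' @param reference_scale,base_area see [sample_population()].
#' @param gain named list of bulk readout gains (`atp`, `mts`, `cyquant`).
#' @return an object of class `hcs_plate`: a list with `cells` (per-cell
#'   table), `wells` (per-well table: `plate`, `well`, `role`, `compound`,
#'   `conc_molar`, `count_truth`, `atp`, `mts`, `cyquant`), and `truth`
#'   (per-well expected counts and true phenotype-bin fractions, plus the
#'   generating models).
#' @examples
#' pl <- simulate_dose_plate(hcs_scenario("size_doubling_arrest"),
#'                           growth_model(seed_count = 100),
#'                           concentrations = 10^seq(-9, -6, length.out = 8),
#'                           wells_per_conc = 2,
#'                           noise = noise_model(rng_seed = 11))
#' head(pl$wells)
#' @export
simulate_dose_plate <- function(compound, growth, concentrations,
                                wells_per_conc = 2, noise = noise_model(),
                                n_controls = 4, n_blanks = 4,
                                reference_scale = 1000, base_area = 500,
                                gain = list(atp = 1, mts = 0.001, cyquant = 10)) {
  stopifnot(inherits(compound, "compound_model"), inherits(growth, "growth_model"))
  if (length(concentrations) == 0) stop("concentration list must not be empty")
  if (any(concentrations <= 0)) stop("concentrations must be strictly positive")
  if (n_controls < 2) stop("at least 2 vehicle control wells are required")
  untreated <- cycling_mixture()

  conc <- c(rep(0, n_controls), rep(sort(concentrations), each = wells_per_conc))
  role <- c(rep("control", n_controls),
            rep("treated", length(concentrations) * wells_per_conc))
  conc <- c(conc, rep(NA_real_, n_blanks))
  role <- c(role, rep("blank", n_blanks))
  nwell <- length(conc)
  if (nwell > 384) stop("more than 384 wells requested")
  wells <- sprintf("%s%02d", LETTERS[((seq_len(nwell) - 1) %/% 24) + 1],
                   ((seq_len(nwell) - 1) %% 24) + 1)

  cell_list <- vector("list", nwell)
  out <- data.frame(plate = "P1", well = wells, role = role,
                    compound = ifelse(role == "treated", compound$name,
                                      ifelse(role == "control", "DMSO", "blank")),
                    conc_molar = conc, count_truth = NA_real_,
                    atp = NA_real_, mts = NA_real_, cyquant = NA_real_,
                    stringsAsFactors = FALSE)
  truth <- data.frame(well = wells, conc_molar = conc, expected_count = NA_real_,
                      f_subG1 = NA_real_, f_2N = NA_real_, f_S = NA_real_,
                      f_4N = NA_real_, f_gt4N = NA_real_,
                      stringsAsFactors = FALSE)
  bg <- noise$background_level

  for (i in seq_len(nwell)) {
    if (role[i] == "blank") {
      with_local_seed(substream_seed(noise$rng_seed, 100000L + i), {
        out$count_truth[i] <- 0
        out$atp[i] <- 0
        out$mts[i] <- bg * gain$mts * rlnorm1(1, noise$readout_cv)
        out$cyquant[i] <- bg * gain$cyquant * rlnorm1(1, noise$readout_cv)
      })
      cell_list[[i]] <- NULL
      next
    }
    logc <- if (role[i] == "control") -Inf else log10(conc[i])
    mix <- if (is.finite(logc)) dose_mixture(compound, untreated, logc) else untreated
    mu <- expected_count(compound, growth, logc)
    ncell <- with_local_seed(substream_seed(noise$rng_seed, 200000L + i),
                             stats::rpois(1, mu))
    cells <- sample_population(mix, ncell, noise, reference_scale, base_area,
                               well = wells[i], plate = "P1", stream = i)
    cell_list[[i]] <- cells

    with_local_seed(substream_seed(noise$rng_seed, 300000L + i), {
      out$count_truth[i] <- ncell
      out$atp[i] <- gain$atp * sum(cells$area * cells$atp_per_size) *
        rlnorm1(1, noise$readout_cv)
      out$mts[i] <- (gain$mts * sum(cells$area * cells$mts_per_size) +
                       bg * gain$mts) * rlnorm1(1, noise$readout_cv)
      keep <- cells$state != "subG1"
      out$cyquant[i] <- (gain$cyquant * sum(cells$dna_content[keep]) +
                           bg * gain$cyquant) * rlnorm1(1, noise$readout_cv)
    })

    truth$expected_count[i] <- mu
    bins <- Reduce(`+`, Map(function(s, w) w * state_bin_fractions(s),
                            mix$states, mix$weights))
    truth[i, c("f_subG1", "f_2N", "f_S", "f_4N", "f_gt4N")] <- as.list(bins)
  }

  structure(list(cells = do.call(rbind, cell_list), wells = out,
                 truth = list(wells = truth, compound = compound,
                              growth = growth, noise = noise,
                              reference_scale = reference_scale,
                              base_area = base_area, gain = gain)),
            class = "hcs_plate")
}

#' @export
print.hcs_plate <- function(x, ...) {
  cat(sprintf("<hcs_plate: %s, %d wells (%d control, %d blank), %d cells>\n",
              x$truth$compound$name, nrow(x$wells),
              sum(x$wells$role == "control"), sum(x$wells$role == "blank"),
              if (is.null(x$cells)) 0L else nrow(x$cells)))
  invisible(x)
}

#' Write / read simulated plate tables
#'
#' The per-cell table is written with the public schema columns only
#' (`plate`, `well`, `cell_id`, `dna_int`, `area`, `mito_int`, `tmre_int`);
#' ground truth goes to a JSON sidecar.
#'
#' @param plate an `hcs_plate`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "hcs_plate"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cellf <- file.path(dir, "cells.tsv")
  wellf <- file.path(dir, "wells.tsv")
  truthf <- file.path(dir, "truth.json")
  pub <- plate$cells[, c("plate", "well", "cell_id", "dna_int", "area",
                         "mito_int", "tmre_int")]
  utils::write.table(pub, cellf, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(plate$wells, wellf, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tw <- plate$truth$wells
    jsonlite::write_json(list(compound = plate$truth$compound$name,
                              wells = tw), truthf, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(c(cells = cellf, wells = wellf, truth = truthf))
}

#' @rdname write_plate
#' @param path path to a tab-delimited per-cell or per-well table.
#' @export
read_cell_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
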