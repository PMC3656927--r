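#' Define a cell phenotype state
#'
#' A phenotype state describes one sub-population of cells by its DNA content
#' class and its size/metabolism coupling. DNA content is expressed as a
#' multiple of the diploid (2N) amount: G1 cells carry 1.0, S-phase cells a
#' uniform draw in (1, 2), G2/M cells 2.0, endoreduplicated cells 4.0 or 8.0
#' (mixture set by `endoredup_mix`), and late-apoptotic sub-G1 cells a uniform
#' draw in (0.2, 0.75) reflecting nuclear fragmentation and DNA loss.
#'
#' `size_multiplier` is the fold change in cell (cytoplasm) area relative to an
#' untreated G1 cell; `mito_per_area`, `atp_per_size` and `mts_per_size` scale
#' mitochondrial staining, ATP content and MTS reduction per unit area, so that
#' by default all three track cell size. Drug-arrested, enlarged cells are
#' modelled by raising `size_multiplier` (e.g. 2 for a G2-arrest that doubles
#' cell size), which propagates into per-cell mitochondrial mass and bulk
#' ATP/MTS signal.
#'
#' @param label one of `"G1"`, `"S"`, `"G2M"`, `"endoredup"`, `"subG1"`.
#' @param size_multiplier fold change in cell area vs an untreated G1 cell.
#' @param mito_per_area mitochondrial staining intensity per unit area.
#' @param atp_per_size ATP contribution per unit area.
#' @param mts_per_size MTS contribution per unit area.
#' @param tmre_per_area TMRE (membrane potential dye) intensity per unit area.
#' @param endoredup_mix weights for 4N vs 8N DNA content in endoreduplicated
#'   cells (normalized internally); ignored for other labels.
#' @return an object of class `phenotype_state`.
#' @examples
#' g2 <- phenotype_state("G2M", size_multiplier = 2)
#' @export
phenotype_state <- function(label = c("G1", "S", "G2M", "endoredup", "subG1"),
                            size_multiplier = 1,
                            mito_per_area = 1,
                            atp_per_size = 1,
                            mts_per_size = 1,
                            tmre_per_area = 1,
                            endoredup_mix = c(`4N` = 0.25, `8N` = 0.75)) {
  label <- match.arg(label)
  stopifnot(size_multiplier > 0, mito_per_area >= 0,
            atp_per_size >= 0, mts_per_size >= 0, tmre_per_area >= 0)
  if (label == "endoredup") {
    stopifnot(length(endoredup_mix) == 2, all(endoredup_mix >= 0),
              sum(endoredup_mix) > 0)
    endoredup_mix <- endoredup_mix / sum(endoredup_mix)
  }
  structure(list(label = label,
                 size_multiplier = size_multiplier,
                 mito_per_area = mito_per_area,
                 atp_per_size = atp_per_size,
                 mts_per_size = mts_per_size,
                 tmre_per_area = tmre_per_area,
                 endoredup_mix = endoredup_mix),
            class = "phenotype_state")
}

#' @export
print.phenotype_state <- function(x, ...) {
  cat(sprintf("<phenotype_state %s: size x%.2g, mito/area %.2g, ATP/size %.2g>\n",
              x$label, x$size_multiplier, x$mito_per_area, x$atp_per_size))
  invisible(x)
}

#' Build a phenotype mixture
#'
#' A mixture is a weighted set of phenotype states; weights must sum to one.
#'
#' @param states list of [phenotype_state()] objects.
#' @param weights numeric weights, same length as `states`, summing to 1
#'   within `1e-9`.
#' @return an object of class `phenotype_mixture`.
#' @export
phenotype_mixture <- function(states, weights) {
  stopifnot(is.list(states), length(states) == length(weights))
  if (!all(vapply(states, inherits, logical(1), "phenotype_state")))
    stop("all states must be phenotype_state objects")
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("mixture weights must sum to 1 (got ", format(sum(weights)), ")")
  structure(list(states = states, weights = as.numeric(weights)),
            class = "phenotype_mixture")
}

#' @export
print.phenotype_mixture <- function(x, ...) {
  lab <- vapply(x$states, `[[`, character(1), "label")
  cat("<phenotype_mixture: ",
      paste(sprintf("%s=%.3f", lab, x$weights), collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Untreated (vehicle-control) cycling population
#'
#' Default mixture for an asynchronously cycling adherent line:
#' 60% G1, 15% S, 22% G2/M and 3% sub-G1. Sub-G1 cells retain 40% of G1
#' cell area (apoptotic shrinkage). All fractions are configurable.
#'
#' @param g1,s,g2m,subg1 fractions for each state; must sum to 1.
#' @param subg1_size area of sub-G1 cells as a fraction of G1 area.
#' @return a `phenotype_mixture`.
#' @export
cycling_mixture <- function(g1 = 0.60, s = 0.15, g2m = 0.22, subg1 = 0.03,
                            subg1_size = 0.4) {
  phenotype_mixture(
    list(phenotype_state("G1"),
         phenotype_state("S", size_multiplier = 1.2),
         phenotype_state("G2M", size_multiplier = 1.4),
         phenotype_state("subG1", size_multiplier = subg1_size)),
    c(g1, s, g2m, subg1))
}

# weighted blend of mixtures: concatenates the component states and scales
# the weights; used for dose-dependent phenotype interpolation
blend_mixtures <- function(mixtures, weights) {
  keep <- weights > 1e-12
  mixtures <- mixtures[keep]
  weights <- weights[keep]
  weights <- weights / sum(weights)
  states <- do.call(c, lapply(mixtures, `[[`, "states"))
  w <- unlist(mapply(function(m, wt) m$weights * wt, mixtures, weights,
                     SIMPLIFY = FALSE))
  phenotype_mixture(states, w / sum(w))
}

# map a phenotype label to the DNA-content bin its cells predominantly occupy
# (endoreduplicated cells carry 4N or 8N DNA, i.e. normalized content >= 2.5
# only for the 8N part; the 4N part falls in the 4N bin). Used for ground
# truth; returns the expected bin fractions contributed by one state.
state_bin_fractions <- function(state) {
  f <- c(subG1 = 0, `2N` = 0, S = 0, `4N` = 0, gt4N = 0)
  switch(state$label,
         G1 = { f["2N"] <- 1 },
         S = {
           # DNA content uniform on (1,2): bins [1,1.25) -> 2N, [1.25,1.75) -> S,
           # [1.75,2) -> 4N
           f["2N"] <- 0.25; f["S"] <- 0.5; f["4N"] <- 0.25
         },
         G2M = { f["4N"] <- 1 },
         endoredup = { f["gt4N"] <- 1 },
         subG1 = { f["subG1"] <- 1 })
  f
}

# expected DNA content (multiple of 2N) of one state
state_mean_dna <- function(state) {
  switch(state$label,
         G1 = 1, S = 1.5, G2M = 2,
         endoredup = sum(c(4, 8) * state$endoredup_mix),
         subG1 = (0.2 + 0.75) / 2)
}

# draw per-cell DNA content for n cells of one state
draw_dna_content <- function(state, n) {
  switch(state$label,
         G1 = rep(1, n),
         S = stats::runif(n, 1, 2),
         G2M = rep(2, n),
         endoredup = sample(c(4, 8), n, replace = TRUE,
                            prob = state$endoredup_mix),
         subG1 = stats::runif(n, 0.2, 0.75))
}
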