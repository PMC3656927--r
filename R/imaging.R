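# ---- synthetic nuclei/mitochondria field rendering and segmentation ----
# Coordinates are 0-based, row-major; areas in pixels; no physical
# calibration. One single-channel image per field.

new_field_image <- function(pixels, channel, field_index = 1L, well = "A01") {
  stopifnot(is.matrix(pixels), all(pixels >= 0),
            nrow(pixels) >= 64, ncol(pixels) >= 64)
  structure(list(pixels = pixels, channel = channel,
                 field_index = as.integer(field_index), well = well),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image %s %dx%d, well %s field %d, max %.0f>\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$well,
              x$field_index, max(x$pixels)))
  invisible(x)
}


#' Render synthetic microscopy fields from per-cell records
#'
#' Draws each cell as a uniform disc — the nucleus on the DNA channel (area
#' `nucleus_frac` times the cell area, total intensity equal to the cell's
#' `dna_int`) and the full cell on the mitochondria channel (total intensity
#' `mito_int`) — then blurs with a Gaussian point-spread function. The blur
#' conserves integrated intensity, so the pixel sum attributable to each
#' nucleus equals its `dna_int` (cells are kept away from the field border by
#' a margin of four PSF sigmas). When `noise$background_level > 0`, a uniform
#' background is added and every pixel is Poisson-sampled (shot noise).
#'
#' Cells are placed uniformly at random without overlap (centre separations
#' exceed the sum of the cell radii); if the requested density leaves no
#' room, placement fails with an error. Fixed positions can be supplied for
#' constructed fixtures (e.g. touching nuclei).
#'
#' @param cells per-cell table with columns `dna_int`, `area`, `mito_int`
#'   (e.g. from [sample_population()]); may have zero rows.
#' @param width,height field size in pixels (>= 64).
#' @param psf_sigma Gaussian PSF sigma, pixels (> 0).
#' @param noise a [noise_model()]; uses `background_level` and `rng_seed`.
#' @param nucleus_frac nuclear area as a fraction of cell area.
#' @param positions optional n x 2 matrix of 0-based (row, col) centres; skips
#'   random placement and the non-overlap check.
#' @param field_index,well metadata stamped on the images (also offsets the
#'   RNG substream so fields differ).
#' @param channels channels to render.
#' @param max_tries placement attempts per cell before failing.
#' @param gain instrument gain (counts per intensity unit) per channel; the
#'   rendered pixel sum of a cell is `gain * dna_int` (or `gain * mito_int`).
#'   The default mito gain lifts a unit-density cytoplasm well above the
#'   imaging background.
#' @return list with one [field_image][render_field] per channel (`dna`,
#'   `mito`) and `truth`, a data.frame of the placed cells (`cx`, `cy`,
#'   nuclear and cell radii, true intensities).
#' @export
render_field <- function(cells, width = 512, height = 512, psf_sigma = 2,
                         noise = noise_model(), nucleus_frac = 0.35,
                         positions = NULL, field_index = 1L, well = "A01",
                         channels = c("dna", "mito"), max_tries = 500,
                         gain = c(dna = 1, mito = 50)) {
  stopifnot(psf_sigma > 0, width >= 64, height >= 64, nucleus_frac > 0,
            nucleus_frac <= 1)
  n <- nrow(cells)
  r_cell <- if (n) sqrt(cells$area / pi) else numeric(0)
  r_nuc <- if (n) sqrt(nucleus_frac * cells$area / pi) else numeric(0)
  # non-overlap is enforced on the largest rendered footprint: nuclei only
  # when just the DNA channel is drawn, whole cells when mitochondria are too
  r_place <- if ("mito" %in% channels) r_cell else r_nuc
  margin <- r_place + 4 * psf_sigma

  if (is.null(positions) && n > 0) {
    positions <- matrix(NA_real_, n, 2)
    with_local_seed(substream_seed(noise$rng_seed, 400000L + field_index), {
      for (i in seq_len(n)) {
        placed <- FALSE
        for (t in seq_len(max_tries)) {
          cx <- stats::runif(1, margin[i], height - 1 - margin[i])
          cy <- stats::runif(1, margin[i], width - 1 - margin[i])
          if (i == 1 || all((positions[seq_len(i - 1), 1] - cx)^2 +
                              (positions[seq_len(i - 1), 2] - cy)^2 >
                              (r_place[seq_len(i - 1)] + r_place[i] + 2)^2)) {
            positions[i, ] <- c(cx, cy)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("cannot place ", n, " cells in a ", height, "x", width,
               " field without overlap; reduce density")
      }
    })
  }

  render_channel <- function(totals, radii, channel, stream_off) {
    img <- matrix(0, nrow = height, ncol = width)
    for (i in seq_len(n)) {
      # uniform disc whose pixel sum equals the cell's total intensity
      cx <- positions[i, 1]; cy <- positions[i, 2]
      r <- ceiling(radii[i])
      rows <- max(1, floor(cx) - r):min(height, ceiling(cx) + r + 1)
      cols <- max(1, floor(cy) - r):min(width, ceiling(cy) + r + 1)
      dd <- outer((rows - 1) - cx, (cols - 1) - cy,
                  function(a, b) a^2 + b^2) <= radii[i]^2
      npx <- sum(dd)
      if (npx > 0)
        img[rows, cols][dd] <- img[rows, cols][dd] + totals[i] / npx
    }
    img <- pmax(gaussian_blur(img, psf_sigma), 0)
    if (noise$background_level > 0) {
      img <- with_local_seed(
        substream_seed(noise$rng_seed, 500000L + field_index + stream_off), {
          matrix(stats::rpois(length(img), img + noise$background_level),
                 nrow = height)
        })
    }
    new_field_image(pmin(img, 65535), channel, field_index, well)
  }

  out <- list()
  if ("dna" %in% channels)
    out$dna <- render_channel(if (n) gain[["dna"]] * cells$dna_int
                              else numeric(0), r_nuc, "dna", 0L)
  if ("mito" %in% channels)
    out$mito <- render_channel(if (n) gain[["mito"]] * cells$mito_int
                               else numeric(0), r_cell, "mito", 50000L)
  out$truth <- data.frame(cell = seq_len(n),
                          cx = if (n) positions[, 1] else numeric(0),
                          cy = if (n) positions[, 2] else numeric(0),
                          r_nuc = r_nuc, r_cell = r_cell,
                          dna_int = if (n) cells$dna_int else numeric(0),
                          mito_int = if (n) cells$mito_int else numeric(0))
  out
}

# separable Gaussian blur via EBImage; the circular filter boundary conserves
# the pixel sum exactly
gaussian_blur <- function(img, sigma) {
  as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
}

#' Segment nuclei from a DNA-channel field image
#'
#' Otsu thresholding followed by hole filling and a distance-transform
#' watershed to split touching nuclei, with a minimum-area filter. The
#' threshold is accepted only if it clears the background level by five
#' robust standard deviations; blank or saturated fields therefore yield an
#' empty result with a warning rather than an error. Integrated intensities
#' are background-corrected using the median of non-foreground pixels.
#' Border-touching nuclei are kept but flagged so callers can exclude them.
#'
#' @param image a DNA-channel [render_field()] image (or any `field_image`).
#' @param min_area minimum object area, pixels.
#' @param threshold_method currently `"otsu"`.
#' @param watershed_tolerance minimum height of the object peak in the
#'   distance map, passed to the watershed split.
#' @param dilate_px dilation radius (pixels) of the integration region, so
#'   that blur spread just outside the threshold mask is counted; skirt
#'   pixels are assigned to the nearest object.
#' @return data.frame of class `segmented_nuclei`: `object_id`, `cx`, `cy`
#'   (0-based centroid), `area_px`, `integrated_intensity`, `mean_intensity`,
#'   `touches_border`; attributes `labels` (the label matrix) and
#'   `background` (the background estimate).
#' @export
segment_nuclei <- function(image, min_area = 40, threshold_method = "otsu",
                           watershed_tolerance = 0.5, dilate_px = 4) {
  stopifnot(inherits(image, "field_image"))
  threshold_method <- match.arg(threshold_method, "otsu")
  px <- image$pixels
  empty <- data.frame(object_id = integer(0), cx = numeric(0), cy = numeric(0),
                      area_px = integer(0), integrated_intensity = numeric(0),
                      mean_intensity = numeric(0), touches_border = logical(0))
  class(empty) <- c("segmented_nuclei", "data.frame")
  finish_empty <- function(msg) {
    warning(msg)
    attr(empty, "labels") <- matrix(0L, nrow(px), ncol(px))
    attr(empty, "background") <- stats::median(px)
    empty
  }
  if (diff(range(px)) == 0)
    return(finish_empty("blank or saturated field: no nuclei detected"))

  # Otsu on log intensity: nuclei spanning 1x-8x DNA content stay on the
  # foreground side of a single threshold, which raw-scale Otsu would place
  # between the dim and bright nuclei instead of at the background
  lg <- log1p(px) / log1p(65535)
  thr_lg <- EBImage::otsu(EBImage::Image(lg), range = c(0, 1))
  thr <- expm1(thr_lg * log1p(65535))
  # reject thresholds that merely split the background noise
  bg_med <- stats::median(px)
  bg_mad <- stats::mad(px)
  if (thr <= bg_med + 5 * max(bg_mad, 1))
    return(finish_empty("no foreground above background: no nuclei detected"))
  mask <- EBImage::fillHull(px > thr)
  if (mean(mask) > 0.9)
    return(finish_empty("field nearly saturated: no nuclei detected"))

  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- as.matrix(EBImage::imageData(labels))
  bg <- stats::median(px[lab == 0])

  areas <- tabulate(lab)
  keep <- which(areas >= min_area)
  if (!length(keep))
    return(finish_empty("no objects above min_area"))
  # relabel compactly
  map <- integer(length(areas))
  map[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0 & map[pmax(lab, 1)] > 0
  lab2[nz] <- map[lab[nz]]

  idx <- which(lab2 > 0)
  obj <- lab2[idx]
  rows <- (idx - 1) %% nrow(lab2) + 1
  cols <- (idx - 1) %/% nrow(lab2) + 1
  area_px <- tabulate(obj)
  cx <- tapply(rows - 1, obj, mean)
  cy <- tapply(cols - 1, obj, mean)
  meanint <- tapply(px[idx], obj, mean)
  border <- tapply(rows == 1 | rows == nrow(lab2) |
                     cols == 1 | cols == ncol(lab2), obj, any)

  # integrate over a dilated region (nearest-object assignment) so the
  # point-spread skirt outside the threshold mask is recovered
  if (dilate_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate_px) + 1L, "disc")
    mask_d <- EBImage::dilate(lab2 > 0, brush)
    labd <- as.matrix(EBImage::imageData(
      EBImage::propagate(EBImage::Image(px / 65535),
                         seeds = EBImage::Image(lab2),
                         mask = EBImage::Image(mask_d), lambda = 1e-4)))
  } else labd <- lab2
  idd <- which(labd > 0)
  integ <- tapply(px[idd] - bg, labd[idd], sum)[as.character(seq_along(area_px))]
  out <- data.frame(object_id = seq_along(area_px),
                    cx = as.numeric(cx), cy = as.numeric(cy),
                    area_px = area_px,
                    integrated_intensity = pmax(as.numeric(integ), 0),
                    mean_intensity = as.numeric(meanint),
                    touches_border = as.logical(border))
  class(out) <- c("segmented_nuclei", "data.frame")
  attr(out, "labels") <- lab2
  attr(out, "background") <- bg
  out
}

#' Grow cytoplasmic regions from nuclear seeds
#'
#' Assigns a cytoplasmic region to each segmented nucleus by seeded region
#' growing (Voronoi propagation on the mitochondria image) restricted to the
#' mitochondria-channel foreground, the standard "detect cytoplasm" strategy
#' in high-content screening. Regions are disjoint by construction and each
#' contains its seed nucleus. If the mitochondria image has no foreground
#' (all background), the cytoplasm defaults to the nuclear region alone.
#'
#' @param nuclei result of [segment_nuclei()] (carries the label matrix).
#' @param mito_image mitochondria-channel `field_image` with the same
#'   dimensions.
#' @return data.frame: `object_id`, `cyto_area` (pixels, nucleus included),
#'   `mito_integrated` (background-corrected), `mito_mean`; attribute
#'   `labels` holds the cytoplasm label matrix.
#' @export
assign_cytoplasm <- function(nuclei, mito_image) {
  stopifnot(inherits(nuclei, "segmented_nuclei"),
            inherits(mito_image, "field_image"))
  seeds <- attr(nuclei, "labels")
  px <- mito_image$pixels
  if (!all(dim(seeds) == dim(px)))
    stop("mitochondria image dimensions do not match the segmented field")
  if (!nrow(nuclei)) {
    out <- data.frame(object_id = integer(0), cyto_area = integer(0),
                      mito_integrated = numeric(0), mito_mean = numeric(0))
    attr(out, "labels") <- seeds
    return(out)
  }
  # cytoplasm foreground: a loose background-statistics mask (Otsu's class
  # imbalance on a sparse, dim cytoplasm would bite deep into the cell edge),
  # then a per-cell half-maximum trim so the recovered boundary sits at the
  # true edge of the blurred cell body regardless of staining brightness
  bg_med <- stats::median(px)
  bg_mad <- stats::mad(px)
  fg <- matrix(FALSE, nrow(px), ncol(px))
  if (diff(range(px)) > 0) {
    cand <- px > bg_med + 2 * max(bg_mad, 1)
    if (any(cand) && mean(cand) < 0.9) {
      # drop shot-noise specks
      cc <- EBImage::bwlabel(cand)
      sz <- tabulate(cc)
      fg <- matrix(sz[pmax(cc, 1)] >= 9 & cc > 0, nrow(px))
    }
  }
  have_fg <- any(fg)
  mask <- fg | seeds > 0
  ct <- EBImage::propagate(EBImage::Image(px / 65535),
                           seeds = EBImage::Image(seeds),
                           mask = EBImage::Image(mask), lambda = 1e-4)
  lab <- as.matrix(EBImage::imageData(ct))
  if (have_fg) {
    # half-max trim per object: plateau estimated over the seed (nuclear)
    # pixels, which sit at the cell centre on the mitochondria channel
    core <- tapply(px[seeds > 0], seeds[seeds > 0], stats::median)
    thr_i <- (bg_med + core) / 2
    ids_present <- as.integer(names(thr_i))
    thr_map <- rep(Inf, max(lab))
    thr_map[ids_present] <- thr_i
    drop <- lab > 0 & seeds == 0 & px <= thr_map[pmax(lab, 1)]
    lab[drop] <- 0L
  }
  bg <- if (any(lab == 0)) stats::median(px[lab == 0]) else 0
  idx <- which(lab > 0)
  obj <- lab[idx]
  area <- tabulate(obj, nbins = nrow(nuclei))
  integ <- rep(0, nrow(nuclei))
  mn <- rep(NA_real_, nrow(nuclei))
  agg_i <- tapply(px[idx] - bg, obj, sum)
  agg_m <- tapply(px[idx], obj, mean)
  ids <- as.integer(names(agg_i))
  integ[ids] <- pmax(as.numeric(agg_i), 0)
  mn[ids] <- as.numeric(agg_m)
  out <- data.frame(object_id = nuclei$object_id,
                    cyto_area = area[nuclei$object_id],
                    mito_integrated = integ[nuclei$object_id],
                    mito_mean = mn[nuclei$object_id])
  attr(out, "labels") <- lab
  out
}

#' Measure a rendered field back into a per-cell table
#'
#' Full image round-trip: segment nuclei on the DNA channel, optionally grow
#' cytoplasms on the mitochondria channel, and emit rows matching the
#' simulator's per-cell schema.
#'
#' @param dna_image,mito_image `field_image`s (mito optional).
#' @param min_area passed to [segment_nuclei()].
#' @return per-cell data.frame: `plate`, `well`, `cell_id`, `dna_int`,
#'   `area`, `mito_int`, `tmre_int` (NA), `touches_border`.
#' @export
measure_field <- function(dna_image, mito_image = NULL, min_area = 40) {
  nuc <- segment_nuclei(dna_image, min_area = min_area)
  area <- nuc$area_px
  mito <- rep(NA_real_, nrow(nuc))
  if (!is.null(mito_image) && nrow(nuc)) {
    cyto <- assign_cytoplasm(nuc, mito_image)
    area <- cyto$cyto_area
    mito <- cyto$mito_integrated
  }
  data.frame(plate = "P1", well = dna_image$well, cell_id = nuc$object_id,
             dna_int = nuc$integrated_intensity, area = area, mito_int = mito,
             tmre_int = NA_real_, touches_border = nuc$touches_border,
             stringsAsFactors = FALSE)
}

#' Write / read a field image as 16-bit single-channel TIFF
#'
#' Files are named `plate_well_field_channel.tif`.
#'
#' @param image a `field_image`.
#' @param dir output directory.
#' @param plate plate name for the file name.
#' @return the path written (invisibly for the writer).
#' @export
write_field_tiff <- function(image, dir, plate = "P1") {
  stopifnot(inherits(image, "field_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s_%d_%s.tif", plate, image$well,
                                 image$field_index, image$channel))
  EBImage::writeImage(EBImage::Image(image$pixels / 65535), path,
                      type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_field_tiff
#' @param path path to a TIFF written by [write_field_tiff()].
#' @export
read_field_tiff <- function(path) {
  base <- sub("\\.tiff?$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  dat <- EBImage::imageData(EBImage::readImage(path))
  px <- round(matrix(as.numeric(dat), nrow = dim(dat)[1]) * 65535)
  new_field_image(px,
                  channel = parts[length(parts)],
                  field_index = as.integer(parts[length(parts) - 1]),
                  well = parts[2])
}
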