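nz0 <- noise_model(dna_cv = 0, area_cv = 0, background_level = 0, rng_seed = 5)
nzb <- noise_model(dna_cv = 0, area_cv = 0, background_level = 100, rng_seed = 5)
one_g1 <- function(noise = nz0)
  sample_population(phenotype_mixture(list(phenotype_state("G1")), 1), 1,
                    noise, reference_scale = 2e5, base_area = 300)

test_that("rendering conserves integrated intensity and handles empty input", {
  cell <- one_g1()
  f <- render_field(cell, width = 256, height = 256, noise = nz0)
  expect_equal(sum(f$dna$pixels), cell$dna_int, tolerance = 0.01 * cell$dna_int)

  f0 <- render_field(cell[0, ], width = 128, height = 128, noise = nz0)
  expect_true(all(f0$dna$pixels == 0))
  expect_equal(nrow(f0$truth), 0)
})

test_that("overcrowded fields fail with a placement error", {
  cells <- sample_population(phenotype_mixture(list(phenotype_state("G1")), 1),
                             200, nz0, base_area = 2000)
  expect_error(render_field(cells, width = 128, height = 128, noise = nz0),
               "without overlap")
})

test_that("rendered nuclei are re-segmented with full count and accurate intensity", {
  cell <- one_g1(nzb)
  f <- render_field(cell, width = 256, height = 256, noise = nzb)
  seg <- segment_nuclei(f$dna)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$integrated_intensity, cell$dna_int,
               tolerance = 0.02 * cell$dna_int)
  expect_false(seg$touches_border)

  mix <- phenotype_mixture(list(phenotype_state("G1"), phenotype_state("G2M"),
                                phenotype_state("endoredup")),
                           c(0.5, 0.3, 0.2))
  cells <- sample_population(mix, 120, nzb, reference_scale = 2e5,
                             base_area = 300)
  fld <- render_field(cells, width = 1024, height = 1024, noise = nzb)
  seg2 <- segment_nuclei(fld$dna)
  expect_equal(nrow(seg2), 120)
})

test_that("segmented intensity is linear in DNA content across 1x-8x", {
  mix <- phenotype_mixture(list(phenotype_state("G1"), phenotype_state("G2M"),
                                phenotype_state("endoredup")),
                           c(0.4, 0.3, 0.3))
  cells <- sample_population(mix, 100, nzb, reference_scale = 2e5,
                             base_area = 300)
  fld <- render_field(cells, width = 1024, height = 1024, noise = nzb)
  seg <- segment_nuclei(fld$dna)
  expect_equal(nrow(seg), 100)
  m <- vapply(seq_len(nrow(seg)), function(i)
    which.min((fld$truth$cx - seg$cx[i])^2 + (fld$truth$cy - seg$cy[i])^2),
    integer(1))
  truth <- fld$truth$dna_int[m]
  expect_gt(cor(seg$integrated_intensity, truth), 0.999)
  slope <- coef(lm(seg$integrated_intensity ~ truth))[[2]]
  gain <- mean(seg$integrated_intensity / truth)
  expect_lt(abs(slope / gain - 1), 0.02)
})

test_that("count accuracy stays above 98% at 15% field coverage", {
  nn <- noise_model(dna_cv = 0.06, area_cv = 0.1, background_level = 100,
                    rng_seed = 12)
  cells <- sample_population(phenotype_mixture(list(phenotype_state("G1")), 1),
                             340, nn, reference_scale = 2e5, base_area = 300)
  expect_lte(sum(0.35 * cells$area) / 512^2, 0.15)
  f <- render_field(cells, width = 512, height = 512, noise = nn,
                    channels = "dna")
  seg <- segment_nuclei(f$dna)
  expect_gte(nrow(seg) / 340, 0.98)
  expect_lte(nrow(seg) / 340, 1.02)
})

test_that("touching equal nuclei are split by the watershed", {
  cell <- one_g1(nzb)
  two <- cell[c(1, 1), ]
  f <- render_field(two, width = 128, height = 128, noise = nzb,
                    positions = rbind(c(60, 60), c(60, 70)))
  seg <- segment_nuclei(f$dna)
  expect_equal(nrow(seg), 2)
  expect_lt(abs(seg$area_px[1] - seg$area_px[2]) / max(seg$area_px), 0.3)
})

test_that("blank and saturated fields warn and return no objects", {
  blank <- hcscycle:::new_field_image(matrix(0, 128, 128), "dna")
  expect_warning(s <- segment_nuclei(blank), "blank")
  expect_equal(nrow(s), 0)

  noisy <- hcscycle:::new_field_image(
    matrix(rpois(128 * 128, 100), 128, 128), "dna")
  expect_warning(s2 <- segment_nuclei(noisy), "no")
  expect_equal(nrow(s2), 0)

  sat <- hcscycle:::new_field_image(matrix(65535, 128, 128), "dna")
  expect_warning(s3 <- segment_nuclei(sat), "blank or saturated")
  expect_equal(nrow(s3), 0)
})

test_that("cytoplasm regions recover cell area and partition the foreground", {
  cell <- one_g1(nzb)
  f <- render_field(cell, width = 256, height = 256, noise = nzb)
  seg <- segment_nuclei(f$dna)
  cy <- assign_cytoplasm(seg, f$mito)
  expect_equal(cy$cyto_area, cell$area, tolerance = 0.1 * cell$area)

  # all-background mitochondria image: cytoplasm collapses to the nucleus
  blank_mito <- f$mito
  blank_mito$pixels[] <- 100
  cy0 <- assign_cytoplasm(seg, blank_mito)
  expect_equal(cy0$cyto_area, seg$area_px)

  # adjacent cells: disjoint regions, each containing its seed
  two <- cell[c(1, 1), ]
  ft <- render_field(two, width = 256, height = 256, noise = nzb,
                     positions = rbind(c(100, 100), c(100, 125)))
  st <- segment_nuclei(ft$dna)
  ct <- assign_cytoplasm(st, ft$mito)
  lab <- attr(ct, "labels")
  seeds <- attr(st, "labels")
  expect_equal(nrow(ct), 2)
  # each seed pixel keeps its own label -> regions contain their nuclei and
  # cannot overlap
  expect_true(all(lab[seeds > 0] == seeds[seeds > 0]))

  wrong <- hcscycle:::new_field_image(matrix(0, 64, 64), "mito")
  expect_error(assign_cytoplasm(st, wrong), "dimensions")
})

test_that("field images round-trip through 16-bit TIFF", {
  cell <- one_g1(nzb)
  f <- render_field(cell, width = 128, height = 128, noise = nzb)
  dir <- withr::local_tempdir()
  path <- write_field_tiff(f$dna, dir)
  expect_match(basename(path), "^P1_A01_1_dna\\.tif$")
  back <- read_field_tiff(path)
  expect_equal(back$pixels, round(f$dna$pixels), tolerance = 1)
  expect_equal(back$channel, "dna")
  expect_equal(back$well, "A01")
})

test_that("measure_field emits the simulator's per-cell schema", {
  mix <- phenotype_mixture(list(phenotype_state("G1"),
                                phenotype_state("G2M")), c(0.6, 0.4))
  cells <- sample_population(mix, 40, nzb, reference_scale = 2e5,
                             base_area = 300)
  f <- render_field(cells, width = 512, height = 512, noise = nzb,
                    well = "B05")
  tab <- measure_field(f$dna, f$mito)
  expect_named(tab, c("plate", "well", "cell_id", "dna_int", "area",
                      "mito_int", "tmre_int", "touches_border"))
  expect_equal(nrow(tab), 40)
  expect_true(all(tab$well == "B05"))
})
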