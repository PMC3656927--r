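make_control <- function(seed, n = 2000, cv = 0.06, scale = 1000) {
  sample_population(cycling_mixture(), n,
                    noise_model(dna_cv = cv, rng_seed = seed),
                    reference_scale = scale)
}

test_that("2N reference is recovered from noisy controls and exact without noise", {
  ctrl <- make_control(3)
  ref <- estimate_reference(ctrl$dna_int)
  expect_lt(abs(ref$log2_center_2n - log2(1000)), 0.05)

  pure <- sample_population(phenotype_mixture(list(phenotype_state("G1")), 1),
                            500, noise_model(dna_cv = 0, rng_seed = 1),
                            reference_scale = 2048)
  ref0 <- estimate_reference(pure$dna_int)
  expect_equal(ref0$log2_center_2n, 11, tolerance = 0.005)
})

test_that("reference estimation enforces its preconditions", {
  expect_error(estimate_reference(rep(1000, 100)), "at least 200")
  expect_error(estimate_reference(c(rep(1000, 300), -1)), "positive")
})

test_that("ambiguous 2N/4N control histograms resolve to the lower mode with warning", {
  mix <- phenotype_mixture(list(phenotype_state("G1"), phenotype_state("G2M")),
                           c(0.5, 0.5))
  cells <- sample_population(mix, 4000, noise_model(dna_cv = 0.06,
                                                    rng_seed = 44))
  expect_warning(ref <- estimate_reference(cells$dna_int), "lower")
  expect_lt(abs(ref$log2_center_2n - log2(1000)), 0.05)
})

test_that("per-well normalization recenters drift and falls back for pure 4N wells", {
  ref <- estimate_reference(make_control(3)$dna_int)

  # 10% staining drift: per-well peak search recenters the mode at 1
  drift <- sample_population(cycling_mixture(), 2000,
                             noise_model(dna_cv = 0.06, rng_seed = 8),
                             reference_scale = 1100)
  nv <- normalize_well(drift$dna_int, ref)
  expect_false(attr(nv, "fallback"))
  expect_equal(min(peak_centers(nv, min_height = 0.5)), 1, tolerance = 0.02)

  # pure 4N well: no in-range 2N peak, pooled reference used, mode near 2
  p4 <- sample_population(phenotype_mixture(list(phenotype_state("G2M")), 1),
                          2000, noise_model(dna_cv = 0.06, rng_seed = 9))
  nv4 <- normalize_well(p4$dna_int, ref)
  expect_true(attr(nv4, "fallback"))
  expect_equal(peak_centers(nv4, min_height = 0.5), 2, tolerance = 0.1,
               ignore_attr = TRUE)

  # empty well: empty output, flagged
  nv0 <- normalize_well(numeric(0), ref)
  expect_length(nv0, 0)
  expect_true(attr(nv0, "fallback"))
})

test_that("classification bins follow the half-open five-bin scheme", {
  pr <- classify_cells(c(0.5, 1.0, 1.5, 2.0, 3.0), min_cells = 1)
  expect_equal(unname(unlist(pr[c("f_subG1", "f_2N", "f_S", "f_4N",
                                  "f_gt4N")])),
               rep(0.2, 5))
  # boundary values are lower-inclusive
  edges <- classify_cells(c(0.75, 1.25, 1.75, 2.5), min_cells = 1)
  expect_equal(unname(unlist(edges[c("f_2N", "f_S", "f_4N", "f_gt4N")])),
               rep(0.25, 4))
  expect_error(classify_cells(c(1, -0.2)), "positive")
  expect_false(classify_cells(rep(1, 10))$reliable)
  expect_true(classify_cells(rep(1, 50))$reliable)
})

test_that("log2 threshold convention is available behind a flag", {
  # under the log2 reading, content v is binned at 1 + log2(v)
  v <- c(2^(-0.5), 1, 2^0.3, 2^0.9, 2^1.8)   # 1+log2 = 0.5,1,1.3,1.9,2.8
  pr <- classify_cells(v, min_cells = 1, scale = "log2")
  expect_equal(unname(unlist(pr[c("f_subG1", "f_2N", "f_S", "f_4N",
                                  "f_gt4N")])),
               rep(0.2, 5))
})

test_that("fractions sum to one and are invariant to global intensity scaling", {
  ref <- estimate_reference(make_control(3)$dna_int)
  for (seed in c(11, 12, 13)) {
    w <- sample_population(cycling_mixture(), 800,
                           noise_model(dna_cv = 0.06, rng_seed = seed))
    pr <- classify_cells(normalize_well(w$dna_int, ref))
    expect_equal(pr$f_subG1 + pr$f_2N + pr$f_S + pr$f_4N + pr$f_gt4N, 1,
                 tolerance = 1e-12)
    # scale everything (controls and well) by an arbitrary constant
    k <- 3.7
    ctrl2 <- make_control(3)
    ref2 <- estimate_reference(ctrl2$dna_int * k)
    pr2 <- classify_cells(normalize_well(w$dna_int * k, ref2))
    expect_equal(unlist(pr2[3:7]), unlist(pr[3:7]), tolerance = 1e-6)
  }
})

test_that("true mixture fractions are recovered within 3 points", {
  ref <- estimate_reference(make_control(3, n = 4000)$dna_int)
  mix <- phenotype_mixture(
    list(phenotype_state("G1"), phenotype_state("S"), phenotype_state("G2M"),
         phenotype_state("subG1"), phenotype_state("endoredup")),
    c(0.35, 0.2, 0.25, 0.1, 0.1))
  for (seed in c(101, 102, 103, 104, 105)) {
    w <- sample_population(mix, 2000, noise_model(dna_cv = 0.06,
                                                  rng_seed = seed))
    truth <- realized_bin_fractions(w)
    pr <- classify_cells(normalize_well(w$dna_int, ref))
    got <- unname(unlist(pr[c("f_subG1", "f_2N", "f_S", "f_4N", "f_gt4N")]))
    expect_lt(max(abs(got - unname(truth))), 0.03)
  }
})

test_that("normalized 2N/4N/8N peak centers are spaced one log2 unit apart", {
  ref <- estimate_reference(make_control(3)$dna_int)
  mix <- phenotype_mixture(
    list(phenotype_state("G1"), phenotype_state("G2M"),
         phenotype_state("endoredup", endoredup_mix = c(1, 0))),
    c(0.4, 0.3, 0.3))
  s <- sample_population(mix, 6000, noise_model(dna_cv = 0.06, rng_seed = 21))
  pc <- peak_centers(normalize_well(s$dna_int, ref), min_height = 0.2)
  expect_length(pc, 3)
  expect_equal(diff(attr(pc, "log2")), c(1, 1), tolerance = 0.05)
})

test_that("counts normalize to percent of control", {
  expect_equal(count_cells(c(500, 0, 250), c(480, 520)), c(100, 0, 50))
  expect_error(count_cells(10, c(0, 0)), "positive")
  expect_error(count_cells(10, 500), "2 control")
})

test_that("profile_plate recovers an inhibition scenario end to end", {
  conc <- 1e-9 * 2^(0:12)
  pl <- simulate_dose_plate(hcs_scenario("size_doubling_arrest"),
                            growth_model(seed_count = 250,
                                         arrest_efficacy_max = 0.8),
                            conc, 2, noise_model(rng_seed = 33))
  prof <- profile_plate(pl$cells,
                        pl$wells$well[pl$wells$role == "control"])
  expect_equal(sort(prof$well), sort(unique(pl$cells$well)))
  top_wells <- pl$wells$well[which(pl$wells$conc_molar == max(conc))]
  pct <- prof$pct_of_control[prof$well %in% top_wells]
  expect_equal(mean(pct), 20, tolerance = 0.2 * 20 + 3)
  ctrl_pct <- prof$pct_of_control[prof$well %in%
                                    pl$wells$well[pl$wells$role == "control"]]
  expect_equal(mean(ctrl_pct), 100, tolerance = 1e-9)
})
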