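sim_plate <- function(scenario, seed, seed_count = 150,
                      conc = 1e-10 * 2^(0:19)) {
  simulate_dose_plate(hcs_scenario(scenario), growth_model(seed_count = seed_count),
                      conc, 2, noise_model(rng_seed = seed))
}
treated <- function(nw, rd) nw[nw$readout == rd & nw$role == "treated", ]

test_that("percent-of-control arithmetic and error handling", {
  expect_equal(as.numeric(percent_of_control(c(0.9, 0.45), c(0.88, 0.92))),
               c(100, 50), tolerance = 1e-12)
  # MTS-style: blank subtracted first
  v <- percent_of_control(0.5, control_raw = c(0.9, 0.9), blank_raw = 0.1,
                          subtract_background = TRUE)
  expect_equal(as.numeric(v), 50)
  expect_equal(attr(v, "background"), 0.1)
  expect_error(percent_of_control(1, control_raw = 2), "2 control")
  expect_error(percent_of_control(1, c(2, 2), subtract_background = TRUE),
               "blank")
  expect_error(percent_of_control(1, c(0.1, 0.1), blank_raw = 0.5,
                                  subtract_background = TRUE),
               "exceed")
})

test_that("control wells average exactly 100 percent for every readout", {
  pl <- sim_plate("size_doubling_arrest", 7)
  nw <- normalize_plate(pl$wells)
  for (rd in unique(nw$readout)) {
    ctrl <- nw$pct_of_control[nw$role == "control" & nw$readout == rd]
    expect_equal(mean(ctrl), 100, tolerance = 1e-9)
  }
})

test_that("ratio of a series to itself is identically 1", {
  pl <- sim_plate("size_doubling_arrest", 7)
  nw <- normalize_plate(pl$wells)
  cnt <- treated(nw, "count")
  rc <- ratio_curve(cnt, cnt)
  expect_true(all(abs(rc$fold_change - 1) < 1e-12))
  other <- cnt
  other$conc_molar <- other$conc_molar * 1.0001
  expect_error(ratio_curve(other, cnt), "no concentrations")
})

test_that("size-doubling arrest yields a ~2-fold ATP/count plateau and shallower ATP Emax", {
  pl <- sim_plate("size_doubling_arrest", 7)
  nw <- normalize_plate(pl$wells)
  rc <- ratio_curve(treated(nw, "atp"), treated(nw, "count"))
  plateau <- mean(tail(rc$fold_change, 4))
  expect_equal(plateau, 2, tolerance = 0.25)

  gsd <- sd(nw$pct_of_control[nw$role == "control" & nw$readout == "count"])
  cnt <- treated(nw, "count"); atp <- treated(nw, "atp")
  fc <- fit_4pl(log10(cnt$conc_molar), cnt$pct_of_control, global_sd = gsd)
  fa <- fit_4pl(log10(atp$conc_molar), atp$pct_of_control,
                global_sd = sd(nw$pct_of_control[nw$role == "control" &
                                                   nw$readout == "atp"]))
  expect_true(fc$valid)
  emax_count <- 100 - coef(fc)[["bottom"]]
  emax_atp <- 100 - coef(fa)[["bottom"]]
  expect_lt(emax_atp, emax_count)
})

test_that("arrest-to-apoptosis switching produces a bell-shaped ratio curve", {
  pl <- sim_plate("arrest_then_apoptosis", 8)
  nw <- normalize_plate(pl$wells)
  rc <- ratio_curve(treated(nw, "atp"), treated(nw, "count"))
  peak <- which.max(rc$fold_change)
  expect_gt(rc$fold_change[peak], 2)          # pronounced per-cell elevation
  expect_gt(peak, 3)                          # rises from ~1 ...
  expect_lt(peak, nrow(rc) - 2)               # ... and comes back down
  expect_lt(mean(head(rc$fold_change, 3)), 1.3)
  expect_lt(tail(rc$fold_change, 1), 1.3)
})

test_that("total mitochondrial mass arithmetic and ATP coupling", {
  cnt <- data.frame(well = c("A01", "A02", "A03"),
                    role = c("control", "control", "treated"),
                    conc_molar = c(0, 0, 1e-7),
                    pct_of_control = c(100, 100, 50))
  # mito fold 1 everywhere: series equals the count series
  mf1 <- data.frame(well = cnt$well, mito_fold = 1)
  expect_equal(total_mito_mass(cnt, mf1)$pct_of_control, cnt$pct_of_control)
  # count 50% x mito fold 2 -> 100%
  mf2 <- data.frame(well = cnt$well, mito_fold = c(1, 1, 2))
  expect_equal(total_mito_mass(cnt, mf2)$pct_of_control[3], 100)

  # simulator coupling: total mito tracks the ATP readout
  pl <- sim_plate("arrest_then_apoptosis", 8)
  nw <- normalize_plate(pl$wells)
  mf <- mito_fold_per_well(pl$cells,
                           pl$wells$well[pl$wells$role == "control"])
  tm <- total_mito_mass(nw[nw$readout == "count", ], mf)
  m <- merge(tm, nw[nw$readout == "atp", c("well", "pct_of_control")],
             by = "well")
  expect_gt(cor(m$pct_of_control.x, m$pct_of_control.y), 0.99)
})

test_that("format comparison flags reproduce the reporting rules", {
  # large EC50 shift: flagged
  cmp1 <- compare_formats(list(log_ec50 = -6.8, emax = 79),
                          list(log_ec50 = -4.5, emax = 80))
  expect_equal(cmp1$delta_log_ec50, 2.3, tolerance = 1e-9)
  expect_true(cmp1$ec50_flag)
  expect_false(cmp1$emax_flag)

  # censored Emax below reporting limit: flagged on the bound
  cmp2 <- compare_formats(list(log_ec50 = -8.7, emax = 74),
                          list(log_ec50 = censored(-4.6, "gt"),
                               emax = censored(20, "lt")))
  expect_true(cmp2$ec50_flag)
  expect_true(cmp2$emax_flag)
  expect_gte(cmp2$delta_emax, 54)

  # identical fits: no flags
  cmp3 <- compare_formats(list(log_ec50 = -7, emax = 80),
                          list(log_ec50 = -7, emax = 80))
  expect_false(cmp3$ec50_flag); expect_false(cmp3$emax_flag)

  # invalid proxy fit with valid count fit: both flags raised
  cmp4 <- compare_formats(list(log_ec50 = -7, emax = 80),
                          list(log_ec50 = NA, emax = NA, valid = FALSE))
  expect_true(cmp4$ec50_flag); expect_true(cmp4$emax_flag)
  expect_equal(cmp4$reason, "no valid fit")
})

test_that("comparison flags agree with direct recomputation on table-shaped fixtures", {
  fixtures <- list(
    list(count = c(-7.3, 79), proxy = c(-7.1, 44)),   # Emax discrepancy
    list(count = c(-7.7, 85), proxy = c(-6.5, 58)),   # both
    list(count = c(-7.4, 93), proxy = c(-7.3, 97)),   # neither
    list(count = c(-8.9, 87), proxy = c(-8.8, 66)),   # neither
    list(count = c(-5.7, 79), proxy = c(-3.8, 55)))   # ec50
  for (fx in fixtures) {
    cmp <- compare_formats(list(log_ec50 = fx$count[1], emax = fx$count[2]),
                           list(log_ec50 = fx$proxy[1], emax = fx$proxy[2]))
    expect_equal(cmp$ec50_flag, abs(fx$proxy[1] - fx$count[1]) > 1)
    expect_equal(cmp$emax_flag, abs(fx$count[2] - fx$proxy[2]) > 25)
  }
})

test_that("near-total-kill concentrations are dropped from ratio curves", {
  sig <- data.frame(conc_molar = c(1e-8, 1e-7, 1e-6),
                    pct_of_control = c(80, 40, 10))
  cnt <- data.frame(conc_molar = c(1e-8, 1e-7, 1e-6),
                    pct_of_control = c(80, 40, 0.5))
  rc <- ratio_curve(sig, cnt)
  expect_equal(nrow(rc), 2)
  expect_false(1e-6 %in% rc$conc_molar)
})
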