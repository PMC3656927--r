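# Independent oracles and small fixtures shared across tests.

# histogram-bin mode finder: an enumeration-style oracle for peak locations,
# independent of the package's kernel-density peak machinery
hist_modes <- function(x, binwidth = 0.02, min_frac = 0.2) {
  br <- seq(min(x) - binwidth, max(x) + binwidth, by = binwidth)
  h <- hist(x, breaks = br, plot = FALSE)
  y <- h$counts
  n <- length(y)
  pk <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  pk <- pk[y[pk] >= min_frac * max(y)]
  sort(h$mids[pk])
}

# dense grid-search oracle for the robust 4PL fit: profiles the asymptotes by
# robust linear regression (MASS::rlm, bisquare) at each (log_ec50, hill) grid
# node and evaluates the robust loss at a fixed tuning scale, so candidate
# solutions are compared under the same objective
oracle_4pl_loss <- function(x, y, scale, le_step = 0.1, hill_step = 0.1) {
  le_grid <- seq(min(x), max(x), by = le_step)
  hill_grid <- seq(0.6, 3.9, by = hill_step)
  best <- Inf
  for (le in le_grid) {
    for (h in hill_grid) {
      f <- 1 / (1 + 10^(h * (x - le)))
      fit <- tryCatch(suppressWarnings(
        MASS::rlm(y ~ f, psi = MASS::psi.bisquare, maxit = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      p <- c(coef(fit)[1], coef(fit)[2], le, h)
      if (p[2] <= 20 || p[2] >= 100) next
      loss <- hcscycle:::robust_loss_value(x, y, p, scale = scale)
      if (loss < best) best <- loss
    }
  }
  best
}

# plain (non-robust) least-squares 4PL fit under the same constraints, used
# as the comparison baseline for breakdown tests
ols_4pl <- function(x, y, span_limits = c(20, 100), hill_limits = c(0.5, 4)) {
  le_limits <- c(min(x) - 2, max(x) + 2)
  fwd <- function(u, lo, hi) lo + (hi - lo) * plogis(u)
  inv <- function(v, lo, hi) qlogis(pmin(pmax((v - lo) / (hi - lo), 1e-6),
                                         1 - 1e-6))
  sse <- function(par) {
    b <- par[1]
    sp <- fwd(par[2], span_limits[1], span_limits[2])
    le <- fwd(par[3], le_limits[1], le_limits[2])
    h <- fwd(par[4], hill_limits[1], hill_limits[2])
    sum((y - (b + sp / (1 + 10^(h * (x - le)))))^2)
  }
  best <- NULL
  for (le0 in seq(min(x), max(x), by = 1)) {
    for (h0 in c(1, 2)) {
      par <- c(min(y), inv(min(max(max(y) - min(y), 25), 95), span_limits[1],
                           span_limits[2]),
               inv(le0, le_limits[1], le_limits[2]),
               inv(h0, hill_limits[1], hill_limits[2]))
      op <- nlminb(par, sse, control = list(iter.max = 300))
      if (is.null(best) || op$objective < best$objective) best <- op
    }
  }
  c(bottom = best$par[1],
    span = fwd(best$par[2], span_limits[1], span_limits[2]),
    log_ec50 = fwd(best$par[3], le_limits[1], le_limits[2]),
    hill = fwd(best$par[4], hill_limits[1], hill_limits[2]))
}

# realized (noise-free) five-bin composition of a simulated sample, from the
# generator's per-cell ground-truth DNA content
realized_bin_fractions <- function(cells) {
  v <- cells$dna_content
  c(subG1 = mean(v < 0.75),
    `2N` = mean(v >= 0.75 & v < 1.25),
    S = mean(v >= 1.25 & v < 1.75),
    `4N` = mean(v >= 1.75 & v < 2.5),
    gt4N = mean(v >= 2.5))
}

# standard 20-point two-fold dilution grid (log10 molar)
dilution_logconc <- function(top_molar = 5e-5, n = 20) {
  log10(top_molar / 2^((n - 1):0))
}

fourpl_curve <- function(x, bottom, top, log_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (x - log_ec50)))
}
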