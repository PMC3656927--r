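# ---- robust constrained 4-parameter logistic dose-response fitting ----
#
# Model (decreasing response, percent-of-control units):
#   y = bottom + span / (1 + 10^(hill * (x - log_ec50))),   span = top - bottom
# with box constraints 20 < span < 100 and 0.5 < hill < 4 enforced by logistic
# reparameterization, fitted by iteratively rescaled Tukey-biweight loss
# (tuning constant 4.685 x robust scale; scale = normalized MAD of the current
# residuals, re-estimated each outer iteration).

fourpl <- function(x, bottom, span, log_ec50, hill) {
  bottom + span / (1 + 10^(hill * (x - log_ec50)))
}

tukey_rho <- function(r, c) {
  u2 <- pmin((r / c)^2, 1)
  (c^2 / 6) * (1 - (1 - u2)^3)
}

tukey_w <- function(r, c) {
  u2 <- (r / c)^2
  ifelse(u2 < 1, (1 - u2)^2, 0)
}

robust_scale <- function(r, floor = 1e-6) {
  max(1.4826 * stats::median(abs(r)), floor)
}

# the robust loss as a functional of the parameters; by default the scale is
# recomputed from the parameters' own residuals (used to rank multi-start
# candidates), but a fixed scale can be supplied so that two candidate
# solutions are compared under the same tuning constant
robust_loss_value <- function(x, y, par, scale = NULL) {
  r <- y - fourpl(x, par[1], par[2], par[3], par[4])
  s <- if (is.null(scale)) robust_scale(r) else scale
  sum(tukey_rho(r, 4.685 * s))
}

# profile the asymptotes at fixed (log_ec50, hill): the model is linear in
# (bottom, span) given the logistic shape, so a small Tukey-IRLS weighted
# linear regression gives good starting asymptotes for each grid node
profile_asymptotes <- function(x, y, log_ec50, hill) {
  f <- 1 / (1 + 10^(hill * (x - log_ec50)))
  w <- rep(1, length(y))
  b <- min(y); sp <- max(y) - min(y)
  for (it in 1:20) {
    sw <- sum(w); swf <- sum(w * f); swf2 <- sum(w * f^2)
    det <- sw * swf2 - swf^2
    if (!is.finite(det) || abs(det) < 1e-12) break
    swy <- sum(w * y); swfy <- sum(w * f * y)
    b_new <- (swf2 * swy - swf * swfy) / det
    sp_new <- (sw * swfy - swf * swy) / det
    r <- y - b_new - sp_new * f
    w_new <- tukey_w(r, 4.685 * robust_scale(r))
    if (sum(w_new) < 3) break
    done <- abs(b_new - b) < 1e-8 && abs(sp_new - sp) < 1e-8
    b <- b_new; sp <- sp_new; w <- w_new
    if (done) break
  }
  c(bottom = b, span = sp)
}

# box transform helpers
box_fwd <- function(u, lo, hi) lo + (hi - lo) * stats::plogis(u)
box_inv <- function(v, lo, hi) {
  p <- (v - lo) / (hi - lo)
  stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))
}

#' Fit a robust constrained four-parameter logistic dose-response curve
#'
#' Fits the decreasing 4PL model
#' `y = bottom + span / (1 + 10^(hill * (x - log_ec50)))`
#' to percent-of-control responses by Tukey-biweight robust loss
#' (tuning constant 4.685 times the normalized-MAD residual scale,
#' re-estimated each iteration), with the asymptote span constrained to
#' (20, 100) percent and the Hill slope to (0.5, 4) via logistic box
#' reparameterization. Optimization is multi-start: `log_ec50` initial values
#' every 0.5 log10 unit across the tested range crossed with Hill slopes 1 and
#' 2; the best converged solution by final robust loss wins, ties broken by
#' smaller Hill slope then smaller `|log_ec50|`.
#'
#' @param x log10 molar concentrations (default method), or a formula
#'   `response ~ logconc`.
#' @param y normalized responses, percent of control.
#' @param global_sd optional plate noise scale (standard deviation of
#'   control-well responses, percent); when supplied the fit is validity-gated
#'   immediately via [assess_validity()].
#' @param span_limits,hill_limits box constraints.
#' @param data data.frame for the formula method.
#' @param ... passed between methods.
#' @return an object of class `logistic4` with components `coefficients`
#'   (`bottom`, `top`, `log_ec50`, `hill`), `span`, `fitted.values`,
#'   `residuals`, `weights` (final biweight weights), `loss`, `scale`,
#'   `rmse_robust`, `se_log_ec50`, `valid`, `reason`, `converged`, `data`.
#' @examples
#' x <- log10(2) * (0:19) - 10
#' y <- 20 + 80 / (1 + 10^(1 * (x + 7)))
#' fit <- fit_4pl(x, y)
#' coef(fit)
#' @export
fit_4pl <- function(x, ...) UseMethod("fit_4pl")

#' @rdname fit_4pl
#' @export
fit_4pl.formula <- function(x, data = parent.frame(), ...) {
  mf <- stats::model.frame(x, data)
  fit <- fit_4pl.default(mf[[2L]], stats::model.response(mf), ...)
  fit$call <- match.call()
  fit
}

#' @rdname fit_4pl
#' @export
fit_4pl.default <- function(x, y, global_sd = NULL,
                            span_limits = c(20, 100), hill_limits = c(0.5, 4),
                            ...) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 6)
    stop("at least 6 distinct concentrations are required for a 4PL fit")
  le_limits <- c(min(x) - 2, max(x) + 2)

  obj <- function(par, cc) {
    b <- par[1]
    sp <- box_fwd(par[2], span_limits[1], span_limits[2])
    le <- box_fwd(par[3], le_limits[1], le_limits[2])
    h <- box_fwd(par[4], hill_limits[1], hill_limits[2])
    r <- y - fourpl(x, b, sp, le, h)
    sum(tukey_rho(r, cc))
  }
  natural <- function(par) {
    c(bottom = par[1],
      span = box_fwd(par[2], span_limits[1], span_limits[2]),
      log_ec50 = box_fwd(par[3], le_limits[1], le_limits[2]),
      hill = box_fwd(par[4], hill_limits[1], hill_limits[2]))
  }

  starts <- expand.grid(le = seq(min(x), max(x), by = 0.5), hill = c(1, 2))

  # one IRLS round: minimize with the current scale frozen, re-estimate the
  # scale from the new residuals, repeat
  irls <- function(par, rounds, rel.tol) {
    p <- unname(natural(par))
    s <- robust_scale(y - fourpl(x, p[1], p[2], p[3], p[4]))
    conv <- FALSE
    for (it in seq_len(rounds)) {
      op <- stats::nlminb(par, obj, cc = 4.685 * s,
                          control = list(iter.max = 300, rel.tol = rel.tol))
      moved <- max(abs(op$par - par))
      par <- op$par
      p <- unname(natural(par))
      s_new <- robust_scale(y - fourpl(x, p[1], p[2], p[3], p[4]))
      conv <- op$convergence %in% c(0, 1)
      done <- abs(s_new - s) < 1e-9 * (1 + s) && moved < 1e-9
      s <- s_new
      if (done) break
    }
    list(par = par, p = p, conv = conv,
         loss = robust_loss_value(x, y, p))
  }

  # screening pass: one IRLS round from every grid start, then polish the
  # best few candidates to convergence
  cand <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    prof <- profile_asymptotes(x, y, starts$le[i], starts$hill[i])
    b0 <- prof[["bottom"]]
    sp0 <- min(max(prof[["span"]], span_limits[1] + 0.5),
               span_limits[2] - 0.5)
    par <- c(b0,
             box_inv(sp0, span_limits[1], span_limits[2]),
             box_inv(starts$le[i], le_limits[1], le_limits[2]),
             box_inv(starts$hill[i], hill_limits[1], hill_limits[2]))
    cand[[i]] <- irls(par, rounds = 4, rel.tol = 1e-8)
  }
  ord <- order(vapply(cand, `[[`, numeric(1), "loss"))
  polished <- list()
  best <- NULL
  best_loss <- Inf
  any_converged <- FALSE
  for (i in ord[seq_len(min(6, length(ord)))]) {
    fin <- irls(cand[[i]]$par, rounds = 12, rel.tol = 1e-12)
    polished[[length(polished) + 1L]] <- fin
    p <- fin$p
    any_converged <- any_converged || fin$conv
    better <- fin$loss < best_loss * (1 - 1e-9) ||
      (abs(fin$loss - best_loss) <= 1e-9 * (1 + best_loss) && !is.null(best) &&
         (p[4] < best$p[4] - 1e-9 ||
            (abs(p[4] - best$p[4]) <= 1e-9 && abs(p[3]) < abs(best$p[3]))))
    if (is.null(best) || better) {
      best <- list(p = p, conv = fin$conv)
      best_loss <- fin$loss
    }
  }

  # MM-style final stage: freeze the scale at the winning solution's robust
  # residual scale and re-descend the fixed-scale Tukey objective from every
  # polished basin, keeping the fixed-scale minimizer; ties broken by smaller
  # hill then smaller |log_ec50|
  r_best <- y - fourpl(x, best$p[1], best$p[2], best$p[3], best$p[4])
  s_mm <- robust_scale(r_best)
  mm_best <- best$p
  mm_loss <- robust_loss_value(x, y, best$p, scale = s_mm)
  for (fin in polished) {
    op <- stats::nlminb(fin$par, obj, cc = 4.685 * s_mm,
                        control = list(iter.max = 300, rel.tol = 1e-13))
    p_mm <- unname(natural(op$par))
    l_mm <- robust_loss_value(x, y, p_mm, scale = s_mm)
    better <- l_mm < mm_loss * (1 - 1e-9) ||
      (abs(l_mm - mm_loss) <= 1e-9 * (1 + mm_loss) &&
         (p_mm[4] < mm_best[4] - 1e-9 ||
            (abs(p_mm[4] - mm_best[4]) <= 1e-9 &&
               abs(p_mm[3]) < abs(mm_best[3]))))
    if (better) {
      mm_best <- p_mm
      mm_loss <- l_mm
    }
  }
  best$p <- mm_best
  best_loss <- robust_loss_value(x, y, mm_best)

  # final polish: weighted least squares on the biweight-inlier set, kept
  # only when it does not worsen the robust loss (it sharpens near-exact
  # fits to machine precision without touching the outlier rejection)
  p <- best$p
  r <- y - fourpl(x, p[1], p[2], p[3], p[4])
  wfin <- tukey_w(r, 4.685 * max(robust_scale(r), 1e-3))
  par0 <- c(p[1], box_inv(p[2], span_limits[1], span_limits[2]),
            box_inv(p[3], le_limits[1], le_limits[2]),
            box_inv(p[4], hill_limits[1], hill_limits[2]))
  wls <- function(par) {
    q <- natural(par)
    sum(wfin * (y - fourpl(x, q[1], q[2], q[3], q[4]))^2)
  }
  op <- stats::nlminb(par0, wls, control = list(iter.max = 500,
                                                rel.tol = 1e-15))
  p_pol <- unname(natural(op$par))
  # Gauss-Newton steps in the natural parameters finish the job at machine
  # precision where the quasi-Newton surface is too flat
  for (gn in 1:8) {
    r_gn <- y - fourpl(x, p_pol[1], p_pol[2], p_pol[3], p_pol[4])
    J <- fourpl_jacobian(x, p_pol)
    step <- tryCatch(solve(crossprod(J, wfin * J), crossprod(J, wfin * r_gn)),
                     error = function(e) NULL)
    if (is.null(step)) break
    p_try <- p_pol + as.numeric(step)
    inside <- p_try[2] > span_limits[1] && p_try[2] < span_limits[2] &&
      p_try[4] > hill_limits[1] && p_try[4] < hill_limits[2] &&
      p_try[3] > le_limits[1] && p_try[3] < le_limits[2]
    if (!inside) break
    r_try <- y - fourpl(x, p_try[1], p_try[2], p_try[3], p_try[4])
    if (sum(wfin * r_try^2) >= sum(wfin * r_gn^2)) break
    p_pol <- p_try
    if (max(abs(step)) < 1e-12) break
  }
  loss_pol <- robust_loss_value(x, y, p_pol)
  if (loss_pol <= best_loss + 1e-9 * (1 + best_loss)) {
    best$p <- p_pol
    best_loss <- min(best_loss, loss_pol)
  }

  # last fixed-scale descent: the polish optimizes a weighted-LS surrogate,
  # so re-minimize the Tukey objective at the final scale before reporting
  p <- best$p
  r <- y - fourpl(x, p[1], p[2], p[3], p[4])
  s_fin <- robust_scale(r)
  par_fin <- c(p[1], box_inv(p[2], span_limits[1], span_limits[2]),
               box_inv(p[3], le_limits[1], le_limits[2]),
               box_inv(p[4], hill_limits[1], hill_limits[2]))
  op_fin <- stats::nlminb(par_fin, obj, cc = 4.685 * s_fin,
                          control = list(iter.max = 300, rel.tol = 1e-13))
  p_fin <- unname(natural(op_fin$par))
  if (robust_loss_value(x, y, p_fin) <= best_loss + 1e-9 * (1 + best_loss)) {
    best$p <- p_fin
    best_loss <- min(best_loss, robust_loss_value(x, y, p_fin))
  }

  p <- best$p
  names(p) <- c("bottom", "span", "log_ec50", "hill")
  r <- y - fourpl(x, p[1], p[2], p[3], p[4])
  s <- robust_scale(r)
  cc <- 4.685 * s
  w <- tukey_w(r, cc)
  dof <- max(sum(w) - 4, 1)
  rmse <- sqrt(sum(w * r^2) / dof)

  # robust-weighted linearized covariance of the natural parameters
  jac <- fourpl_jacobian(x, p)
  se_le <- tryCatch({
    xtwx <- crossprod(jac, w * jac)
    cv <- rmse^2 * solve(xtwx)
    sqrt(max(cv[3, 3], 0))
  }, error = function(e) Inf)
  if (!is.finite(se_le)) se_le <- Inf

  fit <- structure(list(
    coefficients = c(bottom = unname(p[1]), top = unname(p[1] + p[2]),
                     log_ec50 = unname(p[3]), hill = unname(p[4])),
    span = unname(p[2]),
    fitted.values = fourpl(x, p[1], p[2], p[3], p[4]),
    residuals = r,
    weights = w,
    loss = best_loss,
    scale = s,
    rmse_robust = rmse,
    se_log_ec50 = se_le,
    converged = best$conv && any_converged,
    valid = NA,
    reason = if (best$conv) character(0) else "optimizer did not converge",
    span_limits = span_limits, hill_limits = hill_limits,
    data = list(x = x, y = y),
    call = match.call()), class = "logistic4")
  if (!best$conv) fit$valid <- FALSE
  if (!is.null(global_sd)) {
    v <- assess_validity(fit, global_sd)
    fit$valid <- as.logical(v)
    fit$reason <- c(fit$reason, attr(v, "reasons"))
  }
  fit
}

# analytic jacobian of the 4PL mean wrt (bottom, span, log_ec50, hill)
fourpl_jacobian <- function(x, p) {
  b <- p[1]; sp <- p[2]; le <- p[3]; h <- p[4]
  t10 <- 10^(h * (x - le))
  denom <- (1 + t10)
  f <- 1 / denom
  dfdle <- sp * t10 * h * log(10) / denom^2
  dfdh <- -sp * t10 * (x - le) * log(10) / denom^2
  cbind(bottom = rep(1, length(x)), span = f, log_ec50 = dfdle, hill = dfdh)
}

#' Gate a 4PL fit by the screening validity criteria
#'
#' A fit is accepted when its robust residual RMSE is below 1.5 times the
#' global (plate) standard deviation and the standard error of `log_ec50` is
#' below 1 log10 unit. The robust RMSE plays the role of the normalized
#' residual chi-square root: `sqrt(sum(w r^2) / (sum(w) - 4))` with the final
#' biweight weights.
#'
#' @param fit a `logistic4` object.
#' @param global_sd standard deviation of normalized responses across the
#'   experiment's vehicle-control wells, percent (> 0).
#' @return logical flag, with attribute `reasons` listing failed criteria.
#' @export
assess_validity <- function(fit, global_sd) {
  stopifnot(inherits(fit, "logistic4"))
  if (!is.numeric(global_sd) || length(global_sd) != 1 || global_sd <= 0)
    stop("global_sd must be a single positive number")
  reasons <- character(0)
  if (!isTRUE(fit$converged)) reasons <- c(reasons, "no convergence")
  if (!(fit$rmse_robust < 1.5 * global_sd))
    reasons <- c(reasons,
                 sprintf("robust RMSE %.3g >= 1.5 x global sd (%.3g)",
                         fit$rmse_robust, 1.5 * global_sd))
  if (!(fit$se_log_ec50 < 1))
    reasons <- c(reasons, sprintf("SE logEC50 %.3g >= 1", fit$se_log_ec50))
  structure(length(reasons) == 0, reasons = reasons)
}

#' Extract potency and efficacy from a valid 4PL fit
#'
#' EC90 is the concentration producing 90% of the span effect on the
#' decreasing curve: `log10(EC90) = log_ec50 + log10(9) / hill`. Emax is the
#' maximal percent signal reduction, `100 - bottom`.
#'
#' @param fit a `logistic4` object, ideally validity-gated.
#' @return list with `log_ec50`, `ec90_log10`, `emax_pct_reduction`; all `NA`
#'   for an invalid fit.
#' @export
derive_potency <- function(fit) {
  stopifnot(inherits(fit, "logistic4"))
  if (isFALSE(fit$valid))
    return(list(log_ec50 = NA_real_, ec90_log10 = NA_real_,
                emax_pct_reduction = NA_real_))
  cf <- fit$coefficients
  list(log_ec50 = unname(cf["log_ec50"]),
       ec90_log10 = unname(cf["log_ec50"] + log10(9) / cf["hill"]),
       emax_pct_reduction = unname(100 - cf["bottom"]))
}

#' Detect non-monotonic (rebounding) dose-response series
#'
#' Flags a rebound when, after the replicate-mean response has fallen below
#' `100 - 2 * global_sd`, a later concentration's mean rises again by more
#' than `2 * global_sd` above the running minimum. Also reports monotone
#' segments obtained by a peak/valley split with the same `2 * global_sd`
#' hysteresis, so a fall-rise-fall series yields three segments.
#'
#' @param logconc log10 molar concentrations (replicates allowed).
#' @param response normalized responses, percent of control.
#' @param global_sd plate noise scale, percent.
#' @return list with `nonmonotonic` flag, `segments` data.frame
#'   (`start`, `end`, `direction`) indexed into the sorted unique
#'   concentrations, and `means` (replicate-mean response per concentration).
#' @export
detect_nonmonotonic <- function(logconc, response, global_sd) {
  stopifnot(global_sd > 0)
  m <- tapply(response, logconc, mean)
  xs <- as.numeric(names(m))
  o <- order(xs)
  m <- as.numeric(m[o]); xs <- xs[o]
  k <- length(m)
  res <- list(nonmonotonic = FALSE,
              segments = data.frame(start = 1L, end = k, direction = "flat",
                                    stringsAsFactors = FALSE),
              means = data.frame(logconc = xs, mean_response = m))
  if (k < 8) return(res)
  thr <- 2 * global_sd

  # rebound flag: fall below control band, then rise by > 2 sd
  fallen <- FALSE
  runmin <- Inf
  flag <- FALSE
  for (i in seq_len(k)) {
    if (m[i] < 100 - thr) fallen <- TRUE
    if (fallen) {
      runmin <- min(runmin, m[i])
      if (m[i] > runmin + thr) { flag <- TRUE; break }
    }
  }

  # monotone segments by zigzag with hysteresis thr
  turns <- integer(0)
  dir <- 0L
  ext_i <- 1L
  ext_v <- m[1]
  for (i in 2:k) {
    if (dir >= 0 && m[i] > ext_v) { ext_v <- m[i]; ext_i <- i; if (dir == 0 && m[i] > m[1] + thr) dir <- 1L }
    if (dir <= 0 && m[i] < ext_v) { ext_v <- m[i]; ext_i <- i; if (dir == 0 && m[i] < m[1] - thr) dir <- -1L }
    if (dir > 0 && m[i] < ext_v - thr) { turns <- c(turns, ext_i); dir <- -1L; ext_v <- m[i]; ext_i <- i }
    else if (dir < 0 && m[i] > ext_v + thr) { turns <- c(turns, ext_i); dir <- 1L; ext_v <- m[i]; ext_i <- i }
  }
  bounds <- c(1L, turns, k)
  segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1],
                     stringsAsFactors = FALSE)
  segs$direction <- vapply(seq_len(nrow(segs)), function(j) {
    d <- m[segs$end[j]] - m[segs$start[j]]
    if (d > thr / 2) "rising" else if (d < -thr / 2) "falling" else "flat"
  }, character(1))
  res$nonmonotonic <- flag
  res$segments <- segs
  res
}

# ---- S3 methods for logistic4 ----

#' @export
print.logistic4 <- function(x, digits = 4, ...) {
  cat("Robust constrained 4PL fit (Tukey biweight)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("span %.4g, robust RMSE %.4g, SE logEC50 %.3g, valid: %s\n",
              x$span, x$rmse_robust, x$se_log_ec50,
              if (is.na(x$valid)) "not assessed" else x$valid))
  invisible(x)
}

#' @export
summary.logistic4 <- function(object, ...) {
  pot <- derive_potency(object)
  structure(list(coefficients = object$coefficients, span = object$span,
                 rmse_robust = object$rmse_robust,
                 se_log_ec50 = object$se_log_ec50,
                 loss = object$loss, valid = object$valid,
                 reason = object$reason, potency = pot,
                 n = length(object$data$x)),
            class = "summary.logistic4")
}

#' @export
print.summary.logistic4 <- function(x, ...) {
  cat("Robust constrained 4PL fit\n")
  cat(sprintf("  n = %d points\n", x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("  robust RMSE: %.4g   SE logEC50: %.3g   loss: %.5g\n",
              x$rmse_robust, x$se_log_ec50, x$loss))
  cat(sprintf("  valid: %s%s\n",
              if (is.na(x$valid)) "not assessed" else x$valid,
              if (length(x$reason)) paste0(" (", paste(x$reason, collapse = "; "), ")")
              else ""))
  if (!isFALSE(x$valid))
    cat(sprintf("  logEC50 %.3f, logEC90 %.3f, Emax %.1f%% reduction\n",
                x$potency$log_ec50, x$potency$ec90_log10,
                x$potency$emax_pct_reduction))
  invisible(x)
}

#' @export
coef.logistic4 <- function(object, ...) object$coefficients

#' @export
predict.logistic4 <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
  else if (is.numeric(newdata)) newdata
  else newdata[[1L]]
  cf <- object$coefficients
  unname(fourpl(x, cf[["bottom"]], object$span, cf[["log_ec50"]],
                cf[["hill"]]))
}

#' @export
residuals.logistic4 <- function(object, ...) object$residuals

#' @export
fitted.logistic4 <- function(object, ...) object$fitted.values

#' @export
plot.logistic4 <- function(x, ..., n_grid = 200) {
  d <- x$data
  xx <- seq(min(d$x), max(d$x), length.out = n_grid)
  graphics::plot(d$x, d$y, xlab = "log10 concentration (M)",
                 ylab = "response (% of control)", ...)
  graphics::lines(xx, predict(x, xx), col = "steelblue", lwd = 2)
  graphics::abline(h = x$coefficients[c("bottom", "top")], lty = 3,
                   col = "grey50")
  graphics::abline(v = x$coefficients["log_ec50"], lty = 2, col = "grey50")
  invisible(x)
}
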