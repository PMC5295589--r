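#' Temperature normalisation of bottle pressure
#'
#' Re-expresses a CO2 pressure measured at `temp_c` as the pressure at
#' the reference temperature, using a van 't Hoff scaling of the CO2
#' Henry volatility constant:
#' `p_ref = p_obs * exp(K * (1/T_obs - 1/T_ref))` with temperatures in
#' Kelvin. Pressure measured above the reference temperature is scaled
#' down (CO2 is less soluble when warm, so the same dissolved CO2 shows
#' a higher headspace pressure). Identity when `temp_c == t_ref_c`.
#'
#' @param p_bar observed pressure (bar, >= 0); vectorised.
#' @param temp_c observation temperature (deg C).
#' @param t_ref_c reference temperature (deg C), default 10.
#' @param vant_hoff_K van 't Hoff constant in Kelvin, default 2400 (CO2
#'   solubility enthalpy scale).
#' @return Pressure at the reference temperature (bar).
#' @export
normalize_pressure <- function(p_bar, temp_c, t_ref_c = 10,
                               vant_hoff_K = 2400) {
  if (any(p_bar < 0, na.rm = TRUE)) stop("pressure must be >= 0")
  if (any(temp_c < -273.15) || any(t_ref_c < -273.15))
    stop("non-physical temperature below absolute zero")
  p_bar * exp(vant_hoff_K * (1 / (temp_c + 273.15) - 1 / (t_ref_c + 273.15)))
}

#' The five-parameter logistic curve and its analytic helpers
#'
#' `pl5()` evaluates the asymmetric logistic in its log-time form
#' `P(t) = A + (D - A) / (1 + (t/C)^(-B))^G` (with `P(t <= 0) = A`),
#' `pl5_deriv()` its analytic first derivative, `pl5_max_rate()` the
#' closed-form maximum slope (NA when `B*G <= 1`, where the slope is
#' unbounded at the origin), and `pl5_time_to()` the monotone
#' inversion `P(t) = X` (NA when `X` is outside `(A, D)`).
#'
#' @param t time (days); vectorised.
#' @param D upper asymptote (bar).
#' @param C inflection-scale time (days, > 0).
#' @param B slope shape (> 0).
#' @param G asymmetry (> 0).
#' @param A lower asymptote (bar), default 0.
#' @return `pl5`/`pl5_deriv`: pressure / slope at `t`; `pl5_max_rate`:
#'   list(`rate`, `t_at`); `pl5_time_to`: time (days).
#' @export
pl5 <- function(t, D, C, B, G, A = 0) {
  out <- rep(A, length(t))
  ok <- t > 0
  if (any(ok)) {
    u <- exp(-B * (log(t[ok]) - log(C)))
    out[ok] <- A + (D - A) * exp(-G * log1p(u))
  }
  out
}

#' @rdname pl5
#' @export
pl5_deriv <- function(t, D, C, B, G, A = 0) {
  out <- numeric(length(t))
  ok <- t > 0
  if (any(ok)) {
    u <- exp(-B * (log(t[ok]) - log(C)))
    out[ok] <- (D - A) * G * B * u / (t[ok] * (1 + u)^(G + 1))
  }
  out
}

# in u = (t/C)^(-B) the slope is proportional to
# u^{(B+1)/B} / (1+u)^{G+1}, maximised at u* = (B+1)/(B(G+1)-(B+1))
#' @rdname pl5
#' @export
pl5_max_rate <- function(D, C, B, G, A = 0) {
  den <- B * (G + 1) - (B + 1)
  if (den <= 0) return(list(rate = NA_real_, t_at = NA_real_))
  u <- (B + 1) / den
  t_at <- C * u^(-1 / B)
  list(rate = pl5_deriv(t_at, D, C, B, G, A), t_at = t_at)
}

#' @rdname pl5
#' @export
pl5_time_to <- function(X, D, C, B, G, A = 0) {
  ifelse(X > A & X < D,
         C * (((D - A) / (X - A))^(1 / G) - 1)^(-1 / B),
         NA_real_)
}

#' Fit the five-parameter logistic to one kinetic curve
#'
#' Least-squares fit of `P(t) = A + (D - A)/(1 + (t/C)^(-B))^G` by
#' Levenberg-Marquardt with a deterministic multi-start grid: `D` from
#' the maximum observed pressure, `C` from the time of half-maximum,
#' `B` in {1, 2, 4} and `G` in {0.5, 1, 2}; the best residual sum of
#' squares is kept. The lower asymptote `A` is fixed at 0 by default
#' (a freshly sealed bottle starts at ambient pressure).
#'
#' @param time observation times (days, >= 0, strictly increasing).
#' @param pressure normalised pressures (bar, >= 0).
#' @param A lower asymptote, fixed (default 0).
#' @param maxiter Levenberg-Marquardt iteration cap.
#' @return Object of class `kinetic_fit`: list with `par` (named A, D,
#'   C, B, G), `residual_sd`, `converged`, `n`, `fitted`.
#' @export
fit_5pl <- function(time, pressure, A = 0, maxiter = 200) {
  stopifnot(length(time) == length(pressure))
  keep <- is.finite(time) & is.finite(pressure)
  time <- time[keep]; pressure <- pressure[keep]
  if (length(time) < 5L)
    stop("at least 5 observations are required to fit the 5PL")
  if (any(pressure < 0)) stop("pressures must be non-negative")
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing within a replicate")
  bad <- list(par = c(A = A, D = NA_real_, C = NA_real_, B = NA_real_,
                      G = NA_real_),
              residual_sd = NA_real_, converged = FALSE,
              n = length(time), fitted = rep(NA_real_, length(time)))
  class(bad) <- "kinetic_fit"
  if (sd(pressure) == 0 || max(pressure) <= A) return(bad)

  D0 <- max(pressure)
  half <- A + (D0 - A) / 2
  iC <- which(pressure >= half)[1]
  C0 <- if (is.na(iC) || time[iC] <= 0) max(stats::median(time), 1e-3) else time[iC]
  dat <- data.frame(t = time, p = pressure)
  best <- NULL
  for (B0 in c(1, 2, 4)) for (G0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        p ~ pl5(t, D, C, B, G, A = A), data = dat,
        start = list(D = D0, C = C0, B = B0, G = G0),
        lower = c(D = A + 1e-8, C = 1e-8, B = 1e-8, G = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      dev <- sum(resid(fit)^2)
      if (is.null(best) || dev < best$dev) best <- list(fit = fit, dev = dev)
    }
  }
  if (is.null(best)) return(bad)
  cf <- coef(best$fit)
  npar <- 4L
  rsd <- sqrt(best$dev / max(length(time) - npar, 1L))
  out <- list(par = c(A = A, D = unname(cf["D"]), C = unname(cf["C"]),
                      B = unname(cf["B"]), G = unname(cf["G"])),
              residual_sd = rsd, converged = TRUE, n = length(time),
              fitted = fitted(best$fit))
  class(out) <- "kinetic_fit"
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "kinetic_fit: D=%.4g C=%.4g B=%.4g G=%.4g (A=%.3g), resid SD %.3g, n=%d\n",
      x$par["D"], x$par["C"], x$par["B"], x$par["G"], x$par["A"],
      x$residual_sd, x$n))
  else cat("kinetic_fit: not converged\n")
  invisible(x)
}

#' Predict pressure from a 5PL fit
#' @param object a `kinetic_fit`.
#' @param newdata optional data.frame with column `t` (days).
#' @param ... unused.
#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  tt <- if (is.null(newdata)) NULL else newdata$t
  if (is.null(tt)) return(object$fitted)
  p <- object$par
  pl5(tt, p["D"], p["C"], p["B"], p["G"], p["A"])
}

#' Kinetic traits of a fermentation curve
#'
#' Extracts the five kinetic traits: `Pmax` (upper asymptote, bar),
#' `rate` (maximum of the analytic first derivative, bar/day), and the
#' times to reach each pressure threshold (`t0.5`, `t2`, `t5` by
#' default, days). Threshold times at or above the asymptote are
#' unavailable (NA); so in particular `t5` requires `Pmax > 5`.
#'
#' @param object a `kinetic_fit` (closed-form extraction) or any
#'   monotone curve function `P(t)` (numeric extraction).
#' @param thresholds pressure thresholds (bar), default `c(0.5, 2, 5)`.
#' @param ... passed to methods.
#' @return Named numeric vector `Pmax`, `rate`, `t0.5`, `t2`, `t5`
#'   (names follow the thresholds); NA marks unavailable traits.
#' @export
kinetic_traits <- function(object, thresholds = c(0.5, 2, 5), ...) {
  UseMethod("kinetic_traits")
}

#' @rdname kinetic_traits
#' @export
kinetic_traits.kinetic_fit <- function(object, thresholds = c(0.5, 2, 5),
                                       ...) {
  if (!object$converged)
    stop("traits are withheld for non-converged fits")
  p <- object$par
  tx <- pl5_time_to(thresholds, p["D"], p["C"], p["B"], p["G"], p["A"])
  out <- c(unname(p["D"]), pl5_max_rate(p["D"], p["C"], p["B"], p["G"],
                                        p["A"])$rate, tx)
  names(out) <- c("Pmax", "rate", paste0("t", sub("\\.?0+$", "", format(thresholds))))
  out
}

#' @rdname kinetic_traits
#' @param interval time interval (days) searched for threshold
#'   crossings and the maximum slope when `object` is a function.
#' @param deriv optional analytic derivative function; numeric central
#'   differences are used when absent.
#' @export
kinetic_traits.function <- function(object, thresholds = c(0.5, 2, 5),
                                    interval = c(1e-6, 100), deriv = NULL,
                                    ...) {
  f <- object
  Pmax <- f(interval[2])
  df <- if (is.null(deriv)) {
    h <- 1e-5 * diff(interval)
    function(t) (f(t + h) - f(t - h)) / (2 * h)
  } else deriv
  opt <- optimize(df, interval, maximum = TRUE, tol = 1e-10)
  tx <- vapply(thresholds, function(X) {
    if (X >= Pmax || X <= f(interval[1])) return(NA_real_)
    uniroot(function(t) f(t) - X, interval, tol = 1e-12)$root
  }, numeric(1))
  out <- c(Pmax, opt$objective, tx)
  names(out) <- c("Pmax", "rate", paste0("t", sub("\\.?0+$", "", format(thresholds))))
  out
}

#' Fit kinetics for a table of curves
#'
#' Normalises pressures to the reference temperature, fits the 5PL per
#' strain x replicate, and extracts the kinetic traits. Replicates are
#' fitted independently.
#'
#' @param curves long data.frame with columns `strain`, `replicate`,
#'   `time_days`, `pressure_bar`, `temperature_C`.
#' @param t_ref_c reference temperature (deg C), default 10.
#' @param vant_hoff_K van 't Hoff constant (K), default 2400.
#' @param thresholds pressure thresholds (bar) for the time traits.
#' @param A fixed lower asymptote (bar).
#' @return list with `traits` (data.frame: strain, replicate, converged,
#'   one column per trait) and `fits` (list of `kinetic_fit`).
#' @export
fit_kinetics <- function(curves, t_ref_c = 10, vant_hoff_K = 2400,
                         thresholds = c(0.5, 2, 5), A = 0) {
  need <- c("strain", "replicate", "time_days", "pressure_bar",
            "temperature_C")
  stopifnot(is.data.frame(curves), all(need %in% names(curves)))
  curves$p_norm <- normalize_pressure(curves$pressure_bar,
                                      curves$temperature_C,
                                      t_ref_c, vant_hoff_K)
  key <- interaction(curves$strain, curves$replicate, drop = TRUE)
  groups <- split(curves, key)
  tnames <- c("Pmax", "rate",
              paste0("t", sub("\\.?0+$", "", format(thresholds))))
  fits <- list()
  rows <- lapply(groups, function(g) {
    g <- g[order(g$time_days), ]
    fit <- tryCatch(fit_5pl(g$time_days, g$p_norm, A = A),
                    error = function(e) NULL)
    id <- paste(g$strain[1], g$replicate[1], sep = "/")
    fits[[id]] <<- fit
    tr <- setNames(rep(NA_real_, length(tnames)), tnames)
    conv <- !is.null(fit) && fit$converged
    if (conv) tr <- kinetic_traits(fit, thresholds)
    cbind(data.frame(strain = g$strain[1], replicate = g$replicate[1],
                     converged = conv, stringsAsFactors = FALSE),
          as.data.frame(as.list(tr), check.names = FALSE))
  })
  traits <- do.call(rbind, rows)
  rownames(traits) <- NULL
  list(traits = traits, fits = fits)
}

#' Per-strain trait means and standard errors over replicates
#'
#' @param traits the `traits` data.frame from [fit_kinetics()].
#' @return data.frame with one row per strain: n_rep and, per trait,
#'   `<trait>` (mean over converged replicates) and `<trait>_se`.
#' @export
strain_traits <- function(traits) {
  tcols <- setdiff(names(traits), c("strain", "replicate", "converged"))
  by_strain <- split(traits[traits$converged, , drop = FALSE],
                     traits$strain[traits$converged])
  rows <- lapply(names(by_strain), function(s) {
    g <- by_strain[[s]]
    out <- data.frame(strain = s, n_rep = nrow(g), stringsAsFactors = FALSE)
    for (tc in tcols) {
      v <- g[[tc]][is.finite(g[[tc]])]
      out[[tc]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(tc, "_se")]] <- if (length(v) > 1) sd(v) / sqrt(length(v))
                                  else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
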