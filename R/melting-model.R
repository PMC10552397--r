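#' Sigmoidal melting model
#'
#' Fraction of soluble (non-denatured) protein as a function of heating
#' temperature, parameterized by lower/upper plateaus, melting point and
#' slope:
#'
#' \deqn{I(T) = I_{min} + (I_{max} - I_{min}) / \{1 + \exp[(T_m/T - 1)\, s\, T_m]\}}
#'
#' Temperatures are in degrees Celsius throughout (melting points are
#' reported on the Celsius scale and the fit grid is a Celsius grid).
#' For melters `s < 0`, so the curve decreases from `I_max` at low
#' temperature to `I_min` at high temperature, with the midpoint
#' `(I_min + I_max)/2` attained exactly at `T = T_m`.
#'
#' @param params list or `melting_params()` with elements `i_min`, `i_max`,
#'   `tm`, `s`.
#' @param temperature numeric vector of temperatures in degrees C (`> 0`).
#' @return numeric vector of model intensities.
#' @seealso [params_from_ab()] for the equivalent `(a, b)` parameterization.
#' @export
#' @examples
#' melting_model(melting_params(0.1, 1.0, 50, -0.3), 50)  # midpoint 0.55
melting_model <- function(params, temperature) {
  stopifnot(is.numeric(temperature))
  if (any(temperature <= 0, na.rm = TRUE)) {
    stop("temperatures must be positive (degrees C)")
  }
  p <- as_melting_params(params)
  p$i_min + (p$i_max - p$i_min) /
    (1 + exp((p$tm / temperature - 1) * p$s * p$tm))
}

#' Construct a melting parameter set
#'
#' @param i_min,i_max lower/upper plateau intensities (`i_max > i_min`,
#'   `i_min >= 0`).
#' @param tm melting point, degrees C.
#' @param s slope parameter, 1/degC; negative for melters.
#' @return an object of class `melting_params` (a named list).
#' @export
melting_params <- function(i_min, i_max, tm, s) {
  stopifnot(is.numeric(i_min), is.numeric(i_max), is.numeric(tm), is.numeric(s))
  if (i_max <= i_min) stop("i_max must exceed i_min")
  structure(list(i_min = i_min, i_max = i_max, tm = tm, s = s),
            class = "melting_params")
}

as_melting_params <- function(x) {
  if (inherits(x, "melting_params")) return(x)
  if (is.list(x) && all(c("i_min", "i_max", "tm", "s") %in% names(x))) {
    return(structure(x[c("i_min", "i_max", "tm", "s")], class = "melting_params"))
  }
  stop("cannot interpret 'params' as melting parameters")
}

#' @export
print.melting_params <- function(x, ...) {
  cat(sprintf("melting params: I_min=%.4g I_max=%.4g T_m=%.4g degC s=%.4g\n",
              x$i_min, x$i_max, x$tm, x$s))
  invisible(x)
}

#' Convert the (a, b) sigmoid parameterization to (T_m, s)
#'
#' The model can equivalently be written
#' \deqn{I(T) = I_{min} + (I_{max} - I_{min}) / \{1 + \exp[-(a/T - b)]\}}
#' with `T_m = a/b` and `s = -b^2/a`. The inverse mapping is
#' `b = -s * T_m`, `a = -s * T_m^2`.
#'
#' @param a,b scalar parameters of the exponential-argument form; both
#'   nonzero.
#' @return `melting_params` carrying `tm` and `s` (plateaus set to 0/1).
#' @export
params_from_ab <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (a == 0 || b == 0) stop("a and b must be nonzero")
  melting_params(i_min = 0, i_max = 1, tm = a / b, s = -b^2 / a)
}

#' @rdname params_from_ab
#' @param params `melting_params` (only `tm` and `s` are used).
#' @export
ab_from_params <- function(params) {
  p <- as_melting_params(params)
  if (p$tm == 0 || p$s == 0) stop("tm and s must be nonzero for the (a, b) form")
  list(a = -p$s * p$tm^2, b = -p$s * p$tm)
}

## model evaluated directly in the (a, b) form; used by equivalence tests
melting_model_ab <- function(i_min, i_max, a, b, temperature) {
  i_min + (i_max - i_min) / (1 + exp(-(a / temperature - b)))
}

#' Fit the melting model to (temperature, intensity) points
#'
#' Unweighted nonlinear least squares via [minpack.lm::nlsLM()] with a small
#' multi-start grid: melting-point starts at the median observed temperature
#' and at the temperature where the data first cross half-range; slope starts
#' at -0.5 and -0.05; plateau starts from the data minimum and maximum. The
#' four-parameter fit (`i_min`, `i_max`, `tm`, `s`) falls back to a
#' three-parameter fit with `i_min = 0` when no start converges or the
#' four-parameter estimate hits a box bound (`tm` within
#' `[min(T)-10, max(T)+10]`, `i_min >= 0`).
#'
#' @param temperature,intensity numeric vectors of equal length; `NA`
#'   intensities are dropped.
#' @param n_params 4 (default, with 3-parameter fallback) or 3
#'   (`i_min` fixed at 0, no fallback).
#' @param tol parameter convergence tolerance passed to the optimizer.
#' @param log_scale minimize squared residuals of log-intensities instead of
#'   intensities (appropriate when errors are multiplicative); requires
#'   positive data and, in 4-parameter mode, keeps `i_min` positive.
#' @return list with `params` (`melting_params` or `NULL`) and `diagnostics`
#'   (`converged`, `n_params`, `rss`, `n_points`, `start`, `reason`).
#' @export
fit_melting <- function(temperature, intensity, n_params = 4, tol = 1e-8,
                        log_scale = FALSE) {
  stopifnot(length(temperature) == length(intensity), n_params %in% c(3, 4))
  keep <- is.finite(temperature) & is.finite(intensity)
  if (log_scale) keep <- keep & intensity > 0
  temperature <- temperature[keep]
  intensity <- intensity[keep]
  n_distinct_t <- length(unique(temperature))
  if (n_distinct_t < n_params) {
    stop(sprintf("need >= %d distinct temperatures, got %d",
                 n_params, n_distinct_t))
  }

  t_lo <- min(temperature) - 10
  t_hi <- max(temperature) + 10
  y_min <- min(intensity)
  y_max <- max(intensity)
  if (y_max <= 0) {
    return(list(params = NULL, diagnostics = list(
      converged = FALSE, n_params = n_params, rss = NA_real_,
      n_points = length(intensity), start = NA_character_,
      reason = "non-positive data")))
  }

  tm_starts <- c(median = stats::median(temperature),
                 crossing = half_range_crossing(temperature, intensity))
  s_starts <- c(-0.5, -0.05)

  run_fits <- function(fixed_imin) {
    best <- NULL
    for (tn in names(tm_starts)) for (s0 in s_starts) {
      start <- if (fixed_imin) {
        list(i_max = y_max, tm = tm_starts[[tn]], s = s0)
      } else {
        list(i_min = max(y_min, 0), i_max = y_max, tm = tm_starts[[tn]], s = s0)
      }
      form <- if (fixed_imin && log_scale) {
        log(intensity) ~ log(i_max / (1 + exp((tm / temperature - 1) * s * tm)))
      } else if (fixed_imin) {
        intensity ~ i_max / (1 + exp((tm / temperature - 1) * s * tm))
      } else if (log_scale) {
        log(intensity) ~ log(i_min + (i_max - i_min) /
                               (1 + exp((tm / temperature - 1) * s * tm)))
      } else {
        intensity ~ i_min + (i_max - i_min) /
          (1 + exp((tm / temperature - 1) * s * tm))
      }
      imin_floor <- if (log_scale) 1e-9 * y_max else 0
      lower <- if (fixed_imin) c(i_max = 0, tm = t_lo, s = -10) else
        c(i_min = imin_floor, i_max = 0, tm = t_lo, s = -10)
      upper <- if (fixed_imin) c(i_max = Inf, tm = t_hi, s = 10) else
        c(i_min = y_max, i_max = Inf, tm = t_hi, s = 10)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          form, data = data.frame(temperature = temperature,
                                  intensity = intensity),
          start = start, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(
            ptol = tol, ftol = tol, maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(fit = fit, rss = rss,
                     start = sprintf("tm=%s,s=%g", tn, s0))
      }
    }
    best
  }

  finish <- function(best, np, reason = NA_character_) {
    cf <- stats::coef(best$fit)
    i_min <- if (np == 3) 0 else unname(cf["i_min"])
    params <- tryCatch(
      melting_params(i_min, unname(cf["i_max"]), unname(cf["tm"]),
                     unname(cf["s"])),
      error = function(e) NULL)
    list(params = params, diagnostics = list(
      converged = !is.null(params), n_params = np, rss = best$rss,
      n_points = length(intensity), start = best$start, reason = reason))
  }

  if (n_params == 4) {
    best <- run_fits(fixed_imin = FALSE)
    if (!is.null(best)) {
      cf <- stats::coef(best$fit)
      hit_bound <- abs(cf["tm"] - t_lo) < 1e-6 || abs(cf["tm"] - t_hi) < 1e-6
      degenerate <- cf["i_max"] <= cf["i_min"]
      if (!hit_bound && !degenerate) return(finish(best, 4))
      reason <- if (degenerate) "degenerate plateaus" else "tm at bound"
    } else {
      reason <- "4-parameter fit failed"
    }
    if (n_distinct_t >= 3) {
      best3 <- run_fits(fixed_imin = TRUE)
      if (!is.null(best3)) return(finish(best3, 3, reason = reason))
    }
    return(list(params = NULL, diagnostics = list(
      converged = FALSE, n_params = 4, rss = NA_real_,
      n_points = length(intensity), start = NA_character_, reason = reason)))
  }

  best <- run_fits(fixed_imin = TRUE)
  if (is.null(best)) {
    return(list(params = NULL, diagnostics = list(
      converged = FALSE, n_params = 3, rss = NA_real_,
      n_points = length(intensity), start = NA_character_,
      reason = "3-parameter fit failed")))
  }
  finish(best, 3)
}

## temperature at which the mean profile first crosses (min+max)/2,
## linearly interpolated; falls back to the median temperature
half_range_crossing <- function(temperature, intensity) {
  o <- order(temperature)
  tt <- temperature[o]
  yy <- intensity[o]
  agg <- tapply(yy, tt, mean)
  tu <- as.numeric(names(agg))
  yv <- as.numeric(agg)
  half <- (min(yv) + max(yv)) / 2
  above <- yv >= half
  idx <- which(above[-length(above)] != above[-1])
  if (length(idx) == 0) return(stats::median(temperature))
  i <- idx[1]
  t1 <- tu[i]; t2 <- tu[i + 1]; y1 <- yv[i]; y2 <- yv[i + 1]
  if (y2 == y1) return((t1 + t2) / 2)
  t1 + (half - y1) * (t2 - t1) / (y2 - y1)
}

#' Fit a single scaling factor against a frozen melting curve
#'
#' With the melting parameters held fixed, the scaling factor `sf` in
#' `I_i(T) = sf * I_model(T)` has the closed-form least-squares solution
#' `sf = sum(y * m) / sum(m^2)` where `m` are the frozen model values.
#'
#' @param temperature,intensity observed points (`NA` dropped).
#' @param params frozen `melting_params`.
#' @return scalar `sf`; positive whenever the data are positive.
#' @export
fit_scaling_factor <- function(temperature, intensity, params) {
  keep <- is.finite(temperature) & is.finite(intensity)
  temperature <- temperature[keep]
  intensity <- intensity[keep]
  if (length(intensity) < 1) stop("need at least one point")
  m <- melting_model(params, temperature)
  denom <- sum(m^2)
  if (denom == 0) stop("all frozen model values are zero")
  sum(intensity * m) / denom
}
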