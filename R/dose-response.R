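#' Four-parameter log-logistic dose-response model
#'
#' Relative intensity as a function of compound concentration on the
#' `pc = -log10(concentration in M)` axis:
#' \deqn{r(c) = r_{low} + (r_{high} - r_{low}) / (1 + 10^{H (pEC50 - pc)})}
#' At `c = EC50` the response is the plateau midpoint. Parameters are kept
#' in canonical orientation `H < 0`, under which `r_low` is the zero-dose
#' plateau, `r_high` the saturating-dose plateau, and the response direction
#' is `sign(r_high - r_low)`; the `(H, r_low, r_high)` and
#' `(-H, r_high, r_low)` parameterizations describe the same curve.
#'
#' @param params list with `pec50` (-log10 molar EC50), `hill` (H),
#'   `r_low`, `r_high`.
#' @param concentration dose in nM, strictly positive (the vehicle dose has
#'   no log coordinate; it enters only through normalization).
#' @return numeric vector of model responses.
#' @export
dr_model <- function(params, concentration) {
  stopifnot(is.numeric(concentration))
  if (any(concentration <= 0, na.rm = TRUE))
    stop("concentrations must be strictly positive (nM)")
  pc <- 9 - log10(concentration)
  params$r_low + (params$r_high - params$r_low) /
    (1 + 10^(params$hill * (params$pec50 - pc)))
}

#' Convert pEC50 to EC50 in nM
#'
#' `EC50 = 10^(9 - pEC50)` nM; for display the value is rounded to two
#' significant figures.
#'
#' @param pec50 negative decadic logarithm of the molar EC50.
#' @param digits significant figures for display rounding.
#' @return EC50 in nM.
#' @export
pec50_to_ec50 <- function(pec50, digits = 2) {
  stopifnot(is.finite(pec50))
  signif(10^(9 - pec50), digits)
}

dr_start_grid <- function() {
  expand.grid(pec50 = c(9.5, 8.2, 6.8, 5.5),
              hill = c(-3, -0.33, 0.33, 3))
}

#' Fit the dose-response model to (concentration, response) points
#'
#' Best-of-16 multi-start nonlinear least squares over the standard grid of
#' starting values (pEC50 in 9.5, 8.2, 6.8, 5.5; H in -3, -0.33, 0.33, 3),
#' with plateau starts taken from the data ends. The vehicle (0 nM) dose is
#' excluded (no log coordinate). Fit quality is rated by
#' `pseudo-R^2 = 1 - RSS/TSS` with TSS about the mean. Fitted parameters
#' are canonicalized to `H < 0`. pEC50 is constrained to `[4, 12]`; a fit
#' converging on a pEC50 bound is flagged (`on_boundary`) and treated as a
#' non-responder downstream.
#'
#' @param concentration doses in nM (zeros dropped).
#' @param response relative intensities.
#' @return list with `params` (`pec50`, `hill`, `r_low`, `r_high`),
#'   `pseudo_r2`, `diagnostics` (`converged`, `rss`, `n_points`, `start`,
#'   `on_boundary`, `constant`).
#' @export
fit_dose_response <- function(concentration, response) {
  keep <- is.finite(concentration) & is.finite(response) & concentration > 0
  conc <- concentration[keep]
  y <- response[keep]
  if (length(unique(conc)) < 4)
    stop("need >= 4 distinct nonzero concentrations")
  pc <- 9 - log10(conc)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    return(list(params = NULL, pseudo_r2 = 0, diagnostics = list(
      converged = FALSE, rss = 0, n_points = length(y), start = NA_character_,
      on_boundary = FALSE, constant = TRUE)))
  }
  o <- order(pc, decreasing = TRUE)        # high pc = low dose first
  low_end <- mean(y[o][seq_len(min(3, length(y)))])
  high_end <- mean(rev(y[o])[seq_len(min(3, length(y)))])
  grid <- dr_start_grid()
  best <- NULL
  dat <- data.frame(pc = pc, y = y)
  for (g in seq_len(nrow(grid))) {
    # H < 0 start pairs r_low with the low-dose end; H > 0 swaps the roles
    if (grid$hill[g] < 0) {
      start <- list(pec50 = grid$pec50[g], hill = grid$hill[g],
                    r_low = low_end, r_high = high_end)
    } else {
      start <- list(pec50 = grid$pec50[g], hill = grid$hill[g],
                    r_low = high_end, r_high = low_end)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ r_low + (r_high - r_low) / (1 + 10^(hill * (pec50 - pc))),
        data = dat, start = start,
        lower = c(pec50 = 4, hill = -10, r_low = -Inf, r_high = -Inf),
        upper = c(pec50 = 12, hill = 10, r_low = Inf, r_high = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss,
                   start = sprintf("pec50=%g,H=%g", grid$pec50[g],
                                   grid$hill[g]))
    }
  }
  if (is.null(best)) {
    return(list(params = NULL, pseudo_r2 = NA_real_, diagnostics = list(
      converged = FALSE, rss = NA_real_, n_points = length(y),
      start = NA_character_, on_boundary = FALSE, constant = FALSE)))
  }
  cf <- as.list(stats::coef(best$fit))
  if (cf$hill > 0) {            # canonicalize: r_low = zero-dose plateau
    cf <- list(pec50 = cf$pec50, hill = -cf$hill, r_low = cf$r_high,
               r_high = cf$r_low)
  }
  on_boundary <- abs(cf$pec50 - 4) < 1e-6 || abs(cf$pec50 - 12) < 1e-6
  list(params = cf, pseudo_r2 = 1 - best$rss / tss,
       diagnostics = list(converged = TRUE, rss = best$rss,
                          n_points = length(y), start = best$start,
                          on_boundary = on_boundary, constant = FALSE))
}

#' Classify a protein from its 50 degC and 37 degC dose-response fits
#'
#' A protein is a responder when its 50 degC fit reaches the pseudo-R^2
#' threshold (and did not converge on a pEC50 bound); the direction is the
#' sign of `r_high - r_low`. The 37 degC abundance control separates
#' mechanisms: a pure thermal-stability effect melts at 50 degC but is flat
#' at 37 degC (high pseudo-R^2 difference), whereas a pure abundance change
#' shows the same dose response at both temperatures.
#'
#' @param fit_50,fit_37 results of [fit_dose_response()] at the two assay
#'   temperatures.
#' @param threshold pseudo-R^2 responder threshold.
#' @param r2_difference_threshold minimum `pseudo_r2_50 - pseudo_r2_37` for
#'   a pure-stability call.
#' @return list with `direction` (`positive`/`negative`/`none`),
#'   `mechanism` (`stability`/`abundance`/`mixed`/`none`), `pseudo_r2_50`,
#'   `pseudo_r2_37`, `r2_difference`, and the 50 degC `params`.
#' @export
classify_ccr <- function(fit_50, fit_37, threshold = 0.8,
                         r2_difference_threshold = 0.4) {
  r2_50 <- fit_50$pseudo_r2
  r2_37 <- fit_37$pseudo_r2
  r2_diff <- r2_50 - r2_37
  responder <- isTRUE(r2_50 >= threshold) && fit_50$diagnostics$converged &&
    !fit_50$diagnostics$on_boundary
  direction <- "none"
  mechanism <- "none"
  if (responder) {
    direction <- if (fit_50$params$r_high >= fit_50$params$r_low)
      "positive" else "negative"
    dir_37 <- if (fit_37$diagnostics$converged &&
                  !is.null(fit_37$params)) {
      if (fit_37$params$r_high >= fit_37$params$r_low) "positive"
      else "negative"
    } else "none"
    if (isTRUE(r2_diff >= r2_difference_threshold) &&
        isTRUE(r2_37 < threshold)) {
      mechanism <- "stability"
    } else if (isTRUE(r2_37 >= threshold) && dir_37 == direction) {
      mechanism <- "abundance"
    } else {
      mechanism <- "mixed"
    }
  }
  list(direction = direction, mechanism = mechanism,
       pseudo_r2_50 = r2_50, pseudo_r2_37 = r2_37, r2_difference = r2_diff,
       params = fit_50$params)
}

#' Dose-response analysis of a normalized concentration-range matrix
#'
#' Fits every protein at both assay temperatures over all replicate points
#' and classifies responders and mechanisms.
#'
#' @param x `intensity_matrix` of relative intensities
#'   (output of [normalize_ccr()]).
#' @param config `tpp_config()`.
#' @return data frame of class `dose_response_result`, one row per protein:
#'   pEC50, EC50 (nM), Hill slope, plateaus, pseudo-R^2 at both
#'   temperatures, direction and mechanism.
#' @export
analyze_dose_response <- function(x, config = tpp_config("CCR")) {
  stopifnot(inherits(x, "intensity_matrix"))
  ann <- x$annotation
  at <- sort(unique(ann$assay_temperature), decreasing = TRUE)
  if (length(at) != 2)
    stop("expected exactly two assay temperatures, got ",
         paste(at, collapse = ", "))
  hot <- ann$assay_temperature == at[1]
  cold <- ann$assay_temperature == at[2]
  rows <- vector("list", nrow(x$values))
  for (i in seq_len(nrow(x$values))) {
    y <- x$values[i, ]
    f50 <- tryCatch(fit_dose_response(ann$concentration[hot], y[hot]),
                    error = function(e) NULL)
    f37 <- tryCatch(fit_dose_response(ann$concentration[cold], y[cold]),
                    error = function(e) NULL)
    if (is.null(f50) || is.null(f37)) {
      rows[[i]] <- data.frame(
        protein_id = rownames(x$values)[i], pec50 = NA_real_,
        ec50_nm = NA_real_, hill = NA_real_, r_low = NA_real_,
        r_high = NA_real_, pseudo_r2_50 = NA_real_, pseudo_r2_37 = NA_real_,
        r2_difference = NA_real_, direction = "none", mechanism = "none",
        stringsAsFactors = FALSE)
      next
    }
    cl <- classify_ccr(f50, f37, threshold = config$responder_r2_threshold,
                       r2_difference_threshold =
                         config$r2_difference_threshold)
    p <- f50$params
    rows[[i]] <- data.frame(
      protein_id = rownames(x$values)[i],
      pec50 = if (is.null(p)) NA_real_ else p$pec50,
      ec50_nm = if (is.null(p)) NA_real_ else pec50_to_ec50(p$pec50),
      hill = if (is.null(p)) NA_real_ else p$hill,
      r_low = if (is.null(p)) NA_real_ else p$r_low,
      r_high = if (is.null(p)) NA_real_ else p$r_high,
      pseudo_r2_50 = cl$pseudo_r2_50, pseudo_r2_37 = cl$pseudo_r2_37,
      r2_difference = cl$r2_difference, direction = cl$direction,
      mechanism = cl$mechanism, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  class(res) <- c("dose_response_result", class(res))
  res
}
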