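## one-sample t-test on per-replicate log2 ratios with degenerate-variance
## handling: all-zero differences mean "no evidence" (p = 1); zero variance
## around a nonzero mean is reported as the smallest representable p and
## flagged
ratio_t_test <- function(log2_ratios) {
  r <- log2_ratios[is.finite(log2_ratios)]
  n <- length(r)
  if (n < 2) {
    return(list(estimate = if (n) mean(r) else NA_real_, p = NA_real_,
                n = n, degenerate = FALSE))
  }
  if (stats::sd(r) == 0) {
    if (all(r == 0)) {
      return(list(estimate = 0, p = 1, n = n, degenerate = FALSE))
    }
    return(list(estimate = mean(r), p = .Machine$double.xmin, n = n,
                degenerate = TRUE))
  }
  tt <- stats::t.test(r, mu = 0)
  list(estimate = mean(r), p = tt$p.value, n = n, degenerate = FALSE)
}

## matched compound/vehicle log2 ratios of one protein at one temperature,
## one value per replicate
replicate_log2_ratios <- function(y, ann, temperature) {
  sel <- ann$temperature == temperature
  reps <- sort(unique(ann$replicate[sel]))
  vapply(reps, function(r) {
    comp <- y[sel & ann$replicate == r & ann$treatment == "compound"]
    veh <- y[sel & ann$replicate == r & ann$treatment == "vehicle"]
    comp <- comp[is.finite(comp)]; veh <- veh[is.finite(veh)]
    if (!length(comp) || !length(veh)) return(NA_real_)
    log2(mean(comp) / mean(veh))
  }, numeric(1))
}

## protein-level pooled shape fit over all replicates and both arms:
## log y = logA + delta*arm + log(pl + (1-pl) * f(T; tm + dtm*arm, s)).
## The arm offset and melting-point shift keep the plateau ratio and slope
## estimates unbiased for treatment-affected proteins; only the shape
## constants (pl, s, tm) are consumed downstream.
fit_pooled_shape <- function(temperature, intensity, is_compound, start) {
  keep <- is.finite(temperature) & is.finite(intensity) & intensity > 0
  temperature <- temperature[keep]
  intensity <- intensity[keep]
  a <- as.numeric(is_compound[keep])
  if (length(intensity) < 12) return(NULL)
  dat <- data.frame(temperature = temperature, log_y = log(intensity),
                    a = a)
  fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
    log_y ~ log_a + delta * a +
      log(pl + (1 - pl) /
            (1 + exp(((tm + dtm * a) / temperature - 1) * s *
                       (tm + dtm * a)))),
    data = dat,
    start = list(log_a = log(max(intensity)), delta = 0.01,
                 pl = max(start$pl, 1e-4), tm = start$tm, dtm = 0.1,
                 s = start$s),
    lower = c(log_a = -Inf, delta = -10, pl = 1e-6,
              tm = min(temperature) - 10, dtm = -30, s = -10),
    upper = c(log_a = Inf, delta = 10, pl = 0.9,
              tm = max(temperature) + 10, dtm = 30, s = -1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 300))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(pl = unname(cf["pl"]), s = unname(cf["s"]), tm = unname(cf["tm"]))
}

#' Per-temperature compound/vehicle tests for one protein
#'
#' At each temperature, the log2 ratio is the mean over replicates of
#' `log2(compound/vehicle)` within matched (temperature, replicate) pairs;
#' the p-value comes from a paired two-sided t-test of those per-replicate
#' log2 ratios against zero. With fewer than two replicate pairs the ratio
#' is still reported but the p-value is `NA`.
#'
#' @param y named intensity vector for one protein (normalized scale).
#' @param ann sample annotation aligned with `y`.
#' @return data frame with `temperature`, `log2_ratio`, `p`, `n_pairs`,
#'   `degenerate`.
#' @export
per_temperature_tests <- function(y, ann) {
  temps <- sort(unique(ann$temperature))
  rows <- lapply(temps, function(tmp) {
    ratios <- replicate_log2_ratios(y, ann, tmp)
    tt <- ratio_t_test(ratios)
    data.frame(temperature = tmp, log2_ratio = tt$estimate, p = tt$p,
               n_pairs = sum(is.finite(ratios)), degenerate = tt$degenerate)
  })
  do.call(rbind, rows)
}

## single-arm melting fit with the protein's plateau ratio and slope frozen,
## free amplitude and melting point, least squares on the log scale
## (reporter noise is multiplicative, so log residuals are homoscedastic)
fit_arm_tm <- function(temperature, intensity, shape) {
  keep <- is.finite(temperature) & is.finite(intensity) & intensity > 0
  temperature <- temperature[keep]
  intensity <- intensity[keep]
  if (length(unique(temperature)) < 3) return(NA_real_)
  dat <- data.frame(temperature = temperature, log_y = log(intensity))
  pl <- shape$pl
  s <- shape$s
  fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
    log_y ~ log_a + log(pl + (1 - pl) /
                          (1 + exp((tm / temperature - 1) * s * tm))),
    data = dat,
    start = list(log_a = log(max(intensity)), tm = shape$tm),
    lower = c(log_a = -Inf, tm = min(temperature) - 10),
    upper = c(log_a = Inf, tm = max(temperature) + 10),
    control = minpack.lm::nls.lm.control(maxiter = 300))),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  unname(stats::coef(fit)["tm"])
}

## joint paired fit of one replicate (both arms) with frozen shape and a
## single shared amplitude: log y = logA + log(curve(T; tm + dtm*arm)).
## Valid when the protein's abundance is unchanged by treatment, in which
## case paired arms within one TMT set share their scale by construction.
fit_pair_dtm <- function(temperature, intensity, is_compound, shape) {
  keep <- is.finite(temperature) & is.finite(intensity) & intensity > 0
  temperature <- temperature[keep]
  intensity <- intensity[keep]
  a <- as.numeric(is_compound[keep])
  if (sum(a == 0) < 3 || sum(a == 1) < 3) return(c(NA_real_, NA_real_))
  dat <- data.frame(temperature = temperature, log_y = log(intensity), a = a)
  pl <- shape$pl
  s <- shape$s
  fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
    log_y ~ log_a + log(pl + (1 - pl) /
      (1 + exp(((tm + dtm * a) / temperature - 1) * s * (tm + dtm * a)))),
    data = dat,
    # dtm must not start at exactly 0: the numeric-derivative step is
    # value-scaled and would vanish
    start = list(log_a = log(max(intensity)), tm = shape$tm, dtm = 0.1),
    lower = c(log_a = -Inf, tm = min(temperature) - 10, dtm = -30),
    upper = c(log_a = Inf, tm = max(temperature) + 10, dtm = 30),
    control = minpack.lm::nls.lm.control(maxiter = 300))),
    error = function(e) NULL)
  if (is.null(fit)) return(c(NA_real_, NA_real_))
  cf <- stats::coef(fit)
  # a melting point pinned to its box bound is a failed fit
  if (abs(cf["tm"] - (min(temperature) - 10)) < 1e-6 ||
      abs(cf["tm"] - (max(temperature) + 10)) < 1e-6 ||
      abs(abs(cf["dtm"]) - 30) < 1e-6) {
    return(c(NA_real_, NA_real_))
  }
  c(unname(cf["tm"]), unname(cf["tm"] + cf["dtm"]))
}

#' Melting-point shift of one protein
#'
#' Per replicate, melting points are fitted for both arms and the
#' difference (compound minus vehicle) taken; the mean difference and a
#' one-sample t-test against zero across replicates are returned.
#'
#' When a `shape` is supplied (the protein's plateau ratio and slope from
#' its combined melting fit across all labeling sets), the per-replicate
#' fits freeze that shape and work on the log-intensity scale (reporter
#' noise is multiplicative, so log residuals are homoscedastic). Shape is
#' a property of the protein, and conditioning on it makes the
#' per-replicate melting points far better determined from ten points per
#' arm. With `shared_amplitude = TRUE` the two arms of a replicate are fit
#' jointly with one common amplitude and a free melting-point offset --
#' the ratio-based deconvolution: paired arms share their scale within a
#' TMT set whenever protein abundance is unchanged, and imposing that
#' constraint roughly halves the melting-shift variance. It must not be
#' used for proteins with abundance evidence (the caller decides; see
#' [analyze_differential()]). Without a `shape`, free four-parameter
#' [fit_melting()] fits are used per arm (the CETSA path).
#'
#' Replicates in which a fit fails are dropped; fewer than two surviving
#' replicates yield `NA`s.
#'
#' @inheritParams per_temperature_tests
#' @param shape optional list with `pl` (plateau ratio `i_min/i_max`), `s`
#'   and `tm` (starting value) from the protein's combined fit.
#' @param shared_amplitude fit each replicate's arms jointly with a common
#'   amplitude (requires `shape`).
#' @return list with `delta_tm` (mean, degC), `p`, `per_replicate`
#'   (data frame with both arms' melting points), `n`.
#' @export
compute_delta_tm <- function(y, ann, shape = NULL, shared_amplitude = FALSE) {
  reps <- sort(unique(ann$replicate))
  rows <- list()
  for (r in reps) {
    tms <- c(vehicle = NA_real_, compound = NA_real_)
    if (!is.null(shape) && shared_amplitude) {
      sel <- ann$replicate == r
      tms[] <- fit_pair_dtm(ann$temperature[sel], y[sel],
                            ann$treatment[sel] == "compound", shape)
      if (!all(is.finite(tms))) {   # degenerate joint fit: fit arms apart
        for (arm in c("vehicle", "compound")) {
          sel <- ann$replicate == r & ann$treatment == arm
          tms[arm] <- fit_arm_tm(ann$temperature[sel], y[sel], shape)
        }
      }
    } else {
      for (arm in c("vehicle", "compound")) {
        sel <- ann$replicate == r & ann$treatment == arm
        if (!is.null(shape)) {
          tms[arm] <- fit_arm_tm(ann$temperature[sel], y[sel], shape)
        } else {
          fit <- tryCatch(fit_melting(ann$temperature[sel], y[sel]),
                          error = function(e) NULL)
          if (!is.null(fit) && fit$diagnostics$converged)
            tms[arm] <- fit$params$tm
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = r, tm_vehicle = tms["vehicle"], tm_compound = tms["compound"],
      delta_tm = tms["compound"] - tms["vehicle"], row.names = NULL)
  }
  per_rep <- do.call(rbind, rows)
  d <- per_rep$delta_tm[is.finite(per_rep$delta_tm)]
  if (length(d) < 2) {
    return(list(delta_tm = if (length(d)) mean(d) else NA_real_,
                p = NA_real_, per_replicate = per_rep, n = length(d)))
  }
  tt <- ratio_t_test(d)
  list(delta_tm = tt$estimate, p = tt$p, per_replicate = per_rep,
       n = length(d))
}

#' Abundance change of one protein at the lowest temperature
#'
#' At the lowest heating temperature essentially no protein is denatured,
#' so the compound/vehicle ratio there reads out abundance rather than
#' thermal stability.
#'
#' @inheritParams per_temperature_tests
#' @return list with `log2fc`, `p`, `n`.
#' @export
abundance_change <- function(y, ann) {
  t_low <- min(ann$temperature)
  ratios <- replicate_log2_ratios(y, ann, t_low)
  tt <- ratio_t_test(ratios)
  list(log2fc = tt$estimate, p = tt$p, n = tt$n)
}

#' Signed distance score over significant temperatures
#'
#' A combined effect-size summary of the treatment effect on protein
#' intensity collated over temperatures: the signed Euclidean norm of the
#' log2 ratios at temperatures with uncorrected `p < alpha`, signed by their
#' mean. The collation ratio is `2^(mean log2 ratio over those
#' temperatures)`. Zero (ratio `NA`) when no temperature is significant.
#'
#' @param per_temp data frame from [per_temperature_tests()].
#' @param alpha uncorrected per-temperature significance threshold.
#' @return list with `score`, `collation_ratio`, `n_significant`.
#' @export
distance_score <- function(per_temp, alpha = 0.05) {
  sig <- is.finite(per_temp$p) & per_temp$p < alpha
  if (!any(sig)) {
    return(list(score = 0, collation_ratio = NA_real_, n_significant = 0L))
  }
  r <- per_temp$log2_ratio[sig]
  list(score = sign(mean(r)) * sqrt(sum(r^2)),
       collation_ratio = 2^mean(r), n_significant = sum(sig))
}

fisher_combine <- function(p) {
  p <- p[is.finite(p)]
  if (!length(p)) return(NA_real_)
  p <- pmax(p, .Machine$double.xmin)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Classify proteins by combined stability/abundance evidence
#'
#' Protein-level significance combines the per-temperature p-values by
#' Fisher's method and adjusts across proteins by Benjamini-Hochberg;
#' a protein is significant when the adjusted combined p-value falls below
#' `alpha`. Significant proteins are classed by the dominant effect:
#' a melting-point shift with `stab_p < alpha` gives
#' `stabilized`/`destabilized` by the sign of the mean shift, an abundance
#' change with `abund_p < alpha` gives `abundance_up`/`abundance_down`;
#' when both components are individually significant the primary class is
#' the one with the larger standardized effect (|t|), with the other
#' reported as `secondary_class`.
#'
#' @param results data frame with one row per protein carrying
#'   `delta_tm`, `stab_p`, `abundance_log2fc`, `abund_p` and a list-column
#'   `per_temperature` of per-temperature test tables.
#' @param alpha protein-level significance threshold.
#' @return `results` with added `combined_p`, `adj_p`, `significant`,
#'   `class`, `secondary_class`.
#' @export
classify_differential <- function(results, alpha = 0.05) {
  results$combined_p <- vapply(results$per_temperature,
                               function(pt) fisher_combine(pt$p), numeric(1))
  results$adj_p <- stats::p.adjust(results$combined_p, method = "BH")
  results$significant <- is.finite(results$adj_p) & results$adj_p < alpha
  n <- nrow(results)
  cls <- rep("none", n); secondary <- rep("none", n)
  for (i in seq_len(n)) {
    if (!results$significant[i]) next
    stab_sig <- is.finite(results$stab_p[i]) && results$stab_p[i] < alpha
    abund_sig <- is.finite(results$abund_p[i]) && results$abund_p[i] < alpha
    stab_class <- if (isTRUE(results$delta_tm[i] > 0)) "stabilized"
      else "destabilized"
    abund_class <- if (isTRUE(results$abundance_log2fc[i] > 0)) "abundance_up"
      else "abundance_down"
    if (stab_sig && !abund_sig) {
      cls[i] <- stab_class
    } else if (abund_sig && !stab_sig) {
      cls[i] <- abund_class
    } else if (stab_sig && abund_sig) {
      # standardized effect compared on the normal-quantile scale
      t_stab <- abs(stats::qnorm(results$stab_p[i] / 2))
      t_abund <- abs(stats::qnorm(results$abund_p[i] / 2))
      if (t_stab >= t_abund) {
        cls[i] <- stab_class; secondary[i] <- abund_class
      } else {
        cls[i] <- abund_class; secondary[i] <- stab_class
      }
    }
  }
  results$class <- cls
  results$secondary_class <- secondary
  results
}

#' Differential thermal-stability and abundance analysis
#'
#' Runs the per-protein analyses (melting-point shift, lowest-temperature
#' abundance change, per-temperature ratio tests, distance score) over a
#' normalized temperature-range matrix and classifies the proteins.
#'
#' @param x normalized `intensity_matrix` (output of [normalize_tr()]).
#' @param config `tpp_config()`.
#' @param shape_params optional data frame of per-protein combined-fit
#'   parameters (`protein_id`, `i_min`, `i_max`, `tm`, `s`) as produced by
#'   [normalize_tr()]; when present, per-replicate arm fits condition on
#'   each protein's plateau ratio and slope (see [compute_delta_tm()]).
#' @return data frame of class `differential_result`, one row per protein,
#'   with a `per_temperature` list-column.
#' @export
analyze_differential <- function(x, config = tpp_config("TR"),
                                 shape_params = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  ann <- x$annotation
  rows <- vector("list", nrow(x$values))
  for (i in seq_len(nrow(x$values))) {
    y <- x$values[i, ]
    shape <- NULL
    if (!is.null(shape_params)) {
      j <- match(rownames(x$values)[i], shape_params$protein_id)
      if (!is.na(j)) {
        shape <- list(pl = shape_params$i_min[j] / shape_params$i_max[j],
                      s = shape_params$s[j], tm = shape_params$tm[j])
        # refine: the combined fit pools shifted arms, biasing the slope
        # shallow for affected proteins; the pooled fit models the shift
        pooled <- fit_pooled_shape(ann$temperature, y,
                                   ann$treatment == "compound", shape)
        if (!is.null(pooled)) shape <- pooled
      }
    }
    pt <- per_temperature_tests(y, ann)
    ab <- abundance_change(y, ann)
    # arms may share an amplitude unless the lowest-temperature readout
    # calls an abundance change (p < alpha and |log2fc| > 0.1)
    shared <- !is.null(shape) &&
      !(isTRUE(ab$p < config$per_temperature_alpha) &&
          isTRUE(abs(ab$log2fc) > 0.1))
    dt <- compute_delta_tm(y, ann, shape = shape,
                           shared_amplitude = shared)
    ds <- distance_score(pt, alpha = config$per_temperature_alpha)
    rows[[i]] <- data.frame(
      protein_id = rownames(x$values)[i],
      delta_tm = dt$delta_tm, stab_p = dt$p, n_delta_tm = dt$n,
      abundance_log2fc = ab$log2fc, abund_p = ab$p,
      distance_score = ds$score, collation_ratio = ds$collation_ratio,
      n_significant_temps = ds$n_significant, stringsAsFactors = FALSE)
    rows[[i]]$per_temperature <- list(pt)
  }
  res <- do.call(rbind, rows)
  res <- classify_differential(res, alpha = config$significance_alpha)
  class(res) <- c("differential_result", class(res))
  res
}

#' CETSA immunoblot differential melting analysis
#'
#' Band-intensity series (two arms times replicates over the heating grid)
#' are not mutually calibrated, so each series is first normalized by the
#' `i_max` of its own three-parameter melting fit (`i_min = 0`), putting all
#' series on a common 0-1 soluble-fraction scale; the normalized data then
#' run through the same melting-point-shift and per-temperature machinery
#' as the MS pipeline. Series whose fit fails are excluded with a warning.
#'
#' @param series data frame with columns `treatment`
#'   (`"compound"`/`"vehicle"`), `replicate`, `temperature`, `intensity`.
#' @param config `tpp_config()`.
#' @return list with `delta_tm`, `stab_p`, `per_temperature`,
#'   `per_replicate`, `normalized` (the normalized series),
#'   `excluded_series`.
#' @export
analyze_cetsa <- function(series, config = tpp_config("CETSA")) {
  needed <- c("treatment", "replicate", "temperature", "intensity")
  stopifnot(all(needed %in% names(series)))
  if (any(series$intensity < 0, na.rm = TRUE))
    stop("band intensities must be nonnegative")
  series$key <- paste(series$treatment, series$replicate, sep = ":")
  excluded <- character(0)
  norm <- list()
  for (k in unique(series$key)) {
    sub <- series[series$key == k, ]
    fit <- tryCatch(fit_melting(sub$temperature, sub$intensity, n_params = 3),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$diagnostics$converged) {
      warning("melting fit failed for series ", k, "; series excluded")
      excluded <- c(excluded, k)
      next
    }
    sub$intensity <- sub$intensity / fit$params$i_max
    norm[[k]] <- sub
  }
  if (!length(norm)) stop("no CETSA series could be normalized")
  normd <- do.call(rbind, norm)
  ann <- data.frame(temperature = normd$temperature,
                    treatment = normd$treatment,
                    replicate = normd$replicate, stringsAsFactors = FALSE)
  y <- normd$intensity
  pt <- per_temperature_tests(y, ann)
  dt <- compute_delta_tm(y, ann)
  list(delta_tm = dt$delta_tm, stab_p = dt$p, per_temperature = pt,
       per_replicate = dt$per_replicate,
       normalized = normd[, setdiff(names(normd), "key")],
       excluded_series = excluded)
}
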