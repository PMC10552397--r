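#' The standard ten-temperature heating grid
#'
#' Heating temperatures (degC) of the temperature-range design, spanning
#' 36.5-67 degC with the lowest temperature serving as the abundance
#' reference.
#'
#' @return increasing numeric vector of length 10.
#' @export
make_temperature_grid <- function() {
  c(36.5, 41.2, 44.0, 47.1, 49.8, 53.3, 56.0, 59.2, 64.0, 67.0)
}

#' Geometric compound-dilution series
#'
#' A vehicle dose (0 nM) followed by a geometric dilution series ending at
#' `top`. The defaults give the standard ten-dose series
#' 0, 0.098, 0.39, 1.6, 6.2, 25, 100, 400, 1600, 6400 nM (fourfold steps;
#' displayed at 2 significant figures).
#'
#' @param top highest dose, nM.
#' @param steps number of nonzero doses.
#' @param dilution fold change between consecutive doses (> 1).
#' @return numeric vector of length `steps + 1` starting at 0, increasing.
#' @export
make_concentration_series <- function(top = 6400, steps = 9, dilution = 4) {
  stopifnot(top > 0, dilution > 1, steps >= 1)
  c(0, top / dilution^((steps - 1):0))
}

#' Noise model for simulated reporter intensities
#'
#' @param cv coefficient of variation of multiplicative log-normal
#'   measurement noise (>= 0).
#' @param sample_scale_sd standard deviation (log2 units) of per-sample scale
#'   errors shared across proteins -- the pipetting/cell-count errors that
#'   the within-temperature normalization step must remove.
#' @param missing_rate probability that a value drops out (`[0, 1)`).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(cv = 0.1, sample_scale_sd = 0.2, missing_rate = 0.02) {
  stopifnot(cv >= 0, sample_scale_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(cv = cv, sample_scale_sd = sample_scale_sd,
                 missing_rate = missing_rate), class = "noise_model")
}

#' Ground-truth effect-class specification
#'
#' Class proportions and effect sizes used by the simulators. Defaults
#' mirror a proteome in which a small minority of proteins respond to the
#' compound: a stabilization of +2 degC (the scale of a genuine
#' ligand-binding hit on this grid), a matching destabilization, and
#' twofold abundance shifts.
#'
#' @param proportions named numeric vector over
#'   `unaffected`, `stabilized`, `destabilized`, `abundance_up`,
#'   `abundance_down`; must sum to 1.
#' @param delta_tm melting-point shift (degC) for (de)stabilized proteins.
#' @param abundance_log2fc log2 abundance shift for abundance classes.
#' @param pec50 true pEC50 for responders in concentration-range data.
#' @param hill true Hill slope magnitude for responders.
#' @return list of class `truth_spec`.
#' @export
truth_spec <- function(proportions = c(unaffected = 0.85, stabilized = 0.05,
                                       destabilized = 0.04,
                                       abundance_up = 0.03,
                                       abundance_down = 0.03),
                       delta_tm = 2.0, abundance_log2fc = 1.0,
                       pec50 = 8.58, hill = 1.0) {
  classes <- c("unaffected", "stabilized", "destabilized",
               "abundance_up", "abundance_down")
  if (!setequal(names(proportions), classes))
    stop("proportions must be named over: ", paste(classes, collapse = ", "))
  proportions <- proportions[classes]
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  if (any(proportions < 0)) stop("proportions must be nonnegative")
  structure(list(proportions = proportions, delta_tm = delta_tm,
                 abundance_log2fc = abundance_log2fc, pec50 = pec50,
                 hill = hill), class = "truth_spec")
}

## fixed substream indices far above any protein index, so that growing
## n_proteins never reuses or shifts an earlier protein's stream
SCALE_ERR_STREAM <- 1e9
NOISE_STREAM_BASE <- 5e8

## deterministic per-protein substream: adding proteins never perturbs the
## streams of earlier ones (Lehmer-style multiplier, kept below 2^31)
protein_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + as.numeric(index) * 48271) %%
               2147483647)
}

draw_truth <- function(n_proteins, spec, master_seed) {
  if (abs(sum(spec$proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  set.seed(protein_seed(master_seed, 0))
  classes <- names(spec$proportions)
  cls <- sample(classes, n_proteins, replace = TRUE, prob = spec$proportions)
  out <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    set.seed(protein_seed(master_seed, i))
    baseline <- 10^stats::runif(1, 4, 7)      # 3 orders of magnitude
    plateau <- stats::runif(1, 0.02, 0.15)
    tm <- stats::runif(1, 42, 60)
    # slope for a melting transition spanning roughly 8-13 degC
    s <- -stats::runif(1, 0.35, 0.55)
    d_tm <- switch(cls[i], stabilized = spec$delta_tm,
                   destabilized = -spec$delta_tm, 0)
    ab <- switch(cls[i], abundance_up = spec$abundance_log2fc,
                 abundance_down = -spec$abundance_log2fc, 0)
    out[[i]] <- data.frame(
      protein_id = sprintf("P%04d", i), affected_class = cls[i],
      baseline = baseline, i_min_frac = plateau, tm = tm, s = s,
      delta_tm = d_tm, abundance_log2fc = ab,
      pec50 = if (cls[i] == "unaffected") NA_real_ else spec$pec50,
      hill = if (cls[i] == "unaffected") NA_real_ else spec$hill,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

apply_noise <- function(clean, noise, scale_factors, master_seed, offset) {
  sdlog <- sqrt(log(1 + noise$cv^2))
  n <- nrow(clean)
  out <- clean
  for (i in seq_len(n)) {
    set.seed(protein_seed(master_seed, offset + i))
    row <- clean[i, ] * scale_factors
    if (sdlog > 0) row <- row * exp(stats::rnorm(ncol(clean), 0, sdlog))
    if (noise$missing_rate > 0) {
      row[stats::runif(ncol(clean)) < noise$missing_rate] <- NA_real_
    }
    out[i, ] <- row
  }
  out
}

#' Simulate a paired-TMT temperature-range experiment
#'
#' Each value is `baseline * curve(T; arm) * 2^(sample scale error) * noise`,
#' followed by dropout. Compound-arm curves carry the protein's ground-truth
#' melting-point shift and/or abundance shift. One master seed drives
#' everything; per-protein substreams are derived by stable hashing so that
#' increasing `n_proteins` leaves earlier proteins' data unchanged.
#'
#' @param n_proteins number of proteins.
#' @param spec `truth_spec()`.
#' @param noise `noise_model()`.
#' @param design annotation from [build_tr_design()].
#' @param seed master integer seed.
#' @param share_curve if `TRUE`, all proteins share one melting-curve shape
#'   (first protein's plateau/tm/s), varying only in baseline -- useful for
#'   exact-recovery checks where the consensus curve is itself sigmoidal.
#' @return list with `matrix` (`intensity_matrix`) and `truth` (data frame,
#'   one row per protein).
#' @export
simulate_tr_experiment <- function(n_proteins, spec = truth_spec(),
                                   noise = noise_model(),
                                   design = build_tr_design(
                                     make_temperature_grid(), 3),
                                   seed = 1L, share_curve = FALSE) {
  truth <- draw_truth(n_proteins, spec, seed)
  if (share_curve) {
    truth$i_min_frac <- truth$i_min_frac[1]
    truth$tm <- truth$tm[1]
    truth$s <- truth$s[1]
  }
  n_s <- nrow(design)
  set.seed(protein_seed(seed, SCALE_ERR_STREAM))
  scale_err <- stats::rnorm(n_s, 0, noise$sample_scale_sd)
  clean <- matrix(NA_real_, n_proteins, n_s,
                  dimnames = list(truth$protein_id, design$sample_id))
  for (i in seq_len(n_proteins)) {
    tr <- truth[i, ]
    base_params <- melting_params(tr$baseline * tr$i_min_frac, tr$baseline,
                                  tr$tm, tr$s)
    comp_params <- melting_params(
      tr$baseline * tr$i_min_frac * 2^tr$abundance_log2fc,
      tr$baseline * 2^tr$abundance_log2fc, tr$tm + tr$delta_tm, tr$s)
    is_comp <- design$treatment == "compound"
    clean[i, !is_comp] <- melting_model(base_params,
                                        design$temperature[!is_comp])
    clean[i, is_comp] <- melting_model(comp_params,
                                       design$temperature[is_comp])
  }
  vals <- apply_noise(clean, noise, 2^scale_err, seed, NOISE_STREAM_BASE)
  list(matrix = intensity_matrix(vals, design), truth = truth,
       scale_errors = stats::setNames(scale_err, design$sample_id))
}

## four-parameter log-logistic evaluated on the nM axis; dose 0 returns the
## zero-dose plateau limit
dr_curve_nm <- function(pec50, hill, r_low, r_high, conc_nm) {
  out <- numeric(length(conc_nm))
  zero <- conc_nm == 0
  out[zero] <- if (hill < 0) r_low else r_high
  if (any(!zero)) {
    pc <- 9 - log10(conc_nm[!zero])
    out[!zero] <- r_low + (r_high - r_low) / (1 + 10^(hill * (pec50 - pc)))
  }
  out
}

#' Simulate a compound-concentration-range experiment
#'
#' Two heating temperatures (50 degC, where binding-induced stabilization
#' shows as a dose-dependent gain of soluble protein, and a 37 degC
#' abundance control) times ten doses times `replicates`. Stabilized and
#' destabilized proteins follow a log-logistic dose response at 50 degC and
#' stay flat at 37 degC; abundance-affected proteins show the identical dose
#' trend at both temperatures.
#'
#' @inheritParams simulate_tr_experiment
#' @param design annotation from [build_ccr_design()].
#' @param response_amplitude fractional change of the 50 degC level at
#'   saturating dose for (de)stabilized proteins.
#' @return list with `matrix` and `truth`.
#' @export
simulate_ccr_experiment <- function(n_proteins, spec = truth_spec(),
                                    noise = noise_model(),
                                    design = build_ccr_design(),
                                    seed = 1L, response_amplitude = 1.0) {
  truth <- draw_truth(n_proteins, spec, seed)
  n_s <- nrow(design)
  set.seed(protein_seed(seed, SCALE_ERR_STREAM))
  scale_err <- stats::rnorm(n_s, 0, noise$sample_scale_sd)
  clean <- matrix(NA_real_, n_proteins, n_s,
                  dimnames = list(truth$protein_id, design$sample_id))
  for (i in seq_len(n_proteins)) {
    tr <- truth[i, ]
    params <- melting_params(tr$baseline * tr$i_min_frac, tr$baseline,
                             tr$tm, tr$s)
    for (at in unique(design$assay_temperature)) {
      cols <- design$assay_temperature == at
      level <- melting_model(params, at)
      conc <- design$concentration[cols]
      # canonical increasing curve has hill < 0 on the -log10(M) axis
      h <- -abs(tr$hill)
      vals <- switch(tr$affected_class,
        stabilized = if (at >= 50)
          dr_curve_nm(tr$pec50, h, level, level * (1 + response_amplitude),
                      conc) else rep(level, sum(cols)),
        destabilized = if (at >= 50)
          dr_curve_nm(tr$pec50, h, level, level * 0.4, conc)
          else rep(level, sum(cols)),
        abundance_up = dr_curve_nm(tr$pec50, h, level,
                                   level * 2^tr$abundance_log2fc, conc),
        abundance_down = dr_curve_nm(tr$pec50, h, level,
                                     level * 2^tr$abundance_log2fc, conc),
        rep(level, sum(cols)))
      clean[i, cols] <- vals
    }
  }
  vals <- apply_noise(clean, noise, 2^scale_err, seed, NOISE_STREAM_BASE)
  list(matrix = intensity_matrix(vals, design), truth = truth,
       scale_errors = stats::setNames(scale_err, design$sample_id))
}

#' Simulate CETSA immunoblot band-intensity series
#'
#' Densitometry series for one protein: two arms times `replicates`, each on
#' the heating grid, each series on its own arbitrary scale (blots are not
#' mutually calibrated).
#'
#' @param params vehicle-arm `melting_params` on a relative scale.
#' @param delta_tm compound-arm melting-point shift, degC.
#' @param temperatures heating grid.
#' @param replicates number of replicate blots per arm.
#' @param cv multiplicative noise CV.
#' @param seed integer seed.
#' @return data frame with `treatment`, `replicate`, `temperature`,
#'   `intensity`.
#' @export
simulate_cetsa_series <- function(params = melting_params(0.05, 1, 50, -0.45),
                                  delta_tm = 2, temperatures =
                                    make_temperature_grid(),
                                  replicates = 3, cv = 0.05, seed = 1L) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  rows <- list()
  for (trt in c("vehicle", "compound")) for (r in seq_len(replicates)) {
    p <- if (trt == "compound")
      melting_params(params$i_min, params$i_max, params$tm + delta_tm,
                     params$s) else params
    scale <- 10^stats::runif(1, 0, 2)   # arbitrary per-blot scale
    y <- scale * melting_model(p, temperatures)
    if (sdlog > 0) y <- y * exp(stats::rnorm(length(y), 0, sdlog))
    rows[[length(rows) + 1L]] <- data.frame(
      treatment = trt, replicate = r, temperature = temperatures,
      intensity = y, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
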