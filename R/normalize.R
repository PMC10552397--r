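## ---- step 1: within-temperature normalization -------------------------

#' Select the reference sample within one temperature group
#'
#' Among the samples heated at one temperature (two arms times replicates),
#' the reference is the sample to which the others compare positively: the
#' one maximizing the count of positive median log2 fold changes
#' `median(log2(candidate / other))` over all other samples, i.e. the
#' highest-level sample. Ties break to the lowest column index.
#'
#' @param group numeric matrix, proteins x samples (>= 2 columns).
#' @return integer column index of the reference.
#' @export
select_reference_sample <- function(group) {
  stopifnot(is.matrix(group), ncol(group) >= 2)
  n <- ncol(group)
  pos_counts <- integer(n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k == j) next
      shared <- is.finite(group[, j]) & is.finite(group[, k]) &
        group[, j] > 0 & group[, k] > 0
      if (!any(shared)) {
        stop(sprintf("samples %d and %d share no quantified proteins", j, k))
      }
      med <- stats::median(log2(group[shared, j] / group[shared, k]))
      if (med > 0) pos_counts[j] <- pos_counts[j] + 1L
    }
  }
  which.max(pos_counts)   # ties -> lowest index
}

#' Normalize the samples of one temperature group to a common level
#'
#' Each non-reference sample is multiplied by
#' `c = 2^(median log2(reference/sample))`, after which its median log2 fold
#' change against the reference is zero. This removes per-sample scale
#' errors (pipetting, cell-count differences) under the assumption that most
#' proteins are unaffected by treatment, and leaves every within-group
#' protein ratio interpretable.
#'
#' @param group numeric matrix, proteins x samples.
#' @param reference reference column index; default chosen by
#'   [select_reference_sample()].
#' @return list with `group` (normalized matrix), `constants` (per-sample
#'   multipliers) and `reference`.
#' @export
normalize_within_temperature <- function(group,
                                         reference =
                                           select_reference_sample(group)) {
  stopifnot(is.matrix(group))
  constants <- rep(1, ncol(group))
  for (j in seq_len(ncol(group))) {
    if (j == reference) next
    shared <- is.finite(group[, j]) & is.finite(group[, reference]) &
      group[, j] > 0 & group[, reference] > 0
    if (sum(shared) < 3) {
      warning(sprintf(
        "sample %d shares only %d quantified proteins with the reference",
        j, sum(shared)))
    }
    if (!any(shared)) stop(sprintf(
      "sample %d shares no quantified proteins with the reference", j))
    constants[j] <-
      2^stats::median(log2(group[shared, reference] / group[shared, j]))
    group[, j] <- group[, j] * constants[j]
  }
  list(group = group, constants = constants, reference = reference)
}

sample_groups_by_temperature <- function(x) {
  split(x$annotation$sample_id, x$annotation$temperature)
}

#' Step 1 over a whole matrix: normalize within every temperature
#'
#' @param x `intensity_matrix` (temperature-range mode).
#' @param references optional named character vector (temperature ->
#'   sample id) pinning each group's reference sample, e.g. to renormalize
#'   consistently with an earlier run; by default references are selected
#'   by [select_reference_sample()].
#' @return list with `matrix`, per-sample `constants`, and the selected
#'   `reference_samples` per temperature.
#' @export
normalize_tr_step1 <- function(x, references = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  groups <- sample_groups_by_temperature(x)
  vals <- x$values
  constants <- stats::setNames(rep(NA_real_, ncol(vals)), colnames(vals))
  refs <- character(length(groups))
  names(refs) <- names(groups)
  for (tmp in names(groups)) {
    ids <- groups[[tmp]]
    sub <- vals[, ids, drop = FALSE]
    if (is.null(references)) {
      res <- normalize_within_temperature(sub)
    } else {
      ref_idx <- match(references[[tmp]], ids)
      if (is.na(ref_idx)) stop("unknown reference sample for ", tmp)
      res <- normalize_within_temperature(sub, reference = ref_idx)
    }
    vals[, ids] <- res$group
    constants[ids] <- res$constants
    refs[tmp] <- ids[res$reference]
  }
  list(matrix = intensity_matrix(vals, x$annotation),
       constants = constants, reference_samples = refs)
}

## ---- step 2: normalization to a global melting curve -------------------

## mean of the 36 pairwise median log2 fold changes of group_t vs group_low
mean_median_log2fc <- function(group_t, group_low) {
  meds <- c()
  for (j in seq_len(ncol(group_t))) for (k in seq_len(ncol(group_low))) {
    shared <- is.finite(group_t[, j]) & is.finite(group_low[, k]) &
      group_t[, j] > 0 & group_low[, k] > 0
    if (!any(shared)) stop("a sample pair shares no quantified proteins")
    meds <- c(meds, stats::median(log2(group_t[shared, j] /
                                         group_low[shared, k])))
  }
  mean(meds)
}

#' Step 2: shift temperature groups onto a fitted global melting curve
#'
#' For each temperature `T`, the group summary
#' `I(T) = 2^mean(median log2FC(T vs T_low))` is computed from all pairwise
#' comparisons of the samples at `T` with the samples at the lowest
#' temperature. The sigmoidal melting model is fitted to the ten
#' `(T, I(T))` points and every sample in the group at `T` is multiplied by
#' `c(T) = I_fit(T) / I(T)`, placing the group summary exactly on the fitted
#' curve. Because all samples of a group share one constant, no
#' within-temperature ratio changes.
#'
#' @param x `intensity_matrix` after step 1.
#' @return list with `matrix`, `curve` (global `melting_params`),
#'   `constants` (`c(T)` per temperature), and the summary points
#'   `intensity_means` (`I(T)`).
#' @export
normalize_tr_step2 <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  groups <- sample_groups_by_temperature(x)
  temps <- as.numeric(names(groups))
  if (length(temps) < 4) stop("need >= 4 temperatures for the global fit")
  t_low <- as.character(min(temps))
  low_vals <- x$values[, groups[[t_low]], drop = FALSE]
  i_t <- vapply(names(groups), function(tmp) {
    2^mean_median_log2fc(x$values[, groups[[tmp]], drop = FALSE], low_vals)
  }, numeric(1))
  # the summary points are ratio-derived, so their errors are
  # multiplicative; fit on the log scale
  fit <- fit_melting(temps, unname(i_t), log_scale = TRUE)
  if (!fit$diagnostics$converged) {
    stop("global melting-curve fit failed: the data are not melting-shaped")
  }
  c_t <- melting_model(fit$params, temps) / i_t
  names(c_t) <- names(groups)
  vals <- x$values
  for (tmp in names(groups)) {
    vals[, groups[[tmp]]] <- vals[, groups[[tmp]], drop = FALSE] * c_t[tmp]
  }
  list(matrix = intensity_matrix(vals, x$annotation), curve = fit$params,
       constants = c_t, intensity_means = i_t, fit = fit)
}

## ---- step 3: per-protein leveling of labeling sets ----------------------

#' Step 3: level each protein's labeling sets onto its own melting curve
#'
#' Per protein: (a) every labeling set is multiplied by the ratio of the
#' protein's maximum intensity across all sets to its maximum within the
#' set (rough leveling); (b) the melting model is fitted to the combined
#' data of all sets with four parameters, falling back to three parameters
#' (`i_min = 0`) on failure; (c) with the fitted curve frozen, a scaling
#' factor `sf_i` is fitted per set ([fit_scaling_factor()]) and each set is
#' divided by its `sf_i`. Steps (b)-(c) run three times in total to approach
#' self-consistency (stopping early once every `sf_i` is within 1e-6 of 1).
#' Within-set ratios are untouched by construction, so compound/vehicle fold
#' changes survive unchanged.
#'
#' Proteins quantified in fewer than `min_valid_fraction` of the channels of
#' any labeling set are excluded (with a reason), as are proteins whose
#' combined fit fails.
#'
#' @param x `intensity_matrix` after steps 1-2.
#' @param min_valid_fraction per-set quantified-channel fraction required.
#' @param n_iterations total fit/scale iterations.
#' @return list with `matrix` (retained proteins only), `params` (data frame
#'   of final per-protein melting parameters and diagnostics), `sf` (data
#'   frame protein x set x iteration), `excluded` (data frame with reasons).
#' @export
normalize_tr_step3 <- function(x, min_valid_fraction = 0.8,
                               n_iterations = 3) {
  stopifnot(inherits(x, "intensity_matrix"))
  ann <- x$annotation
  sets <- split(seq_len(nrow(ann)), ann$labeling_set)
  temps <- ann$temperature
  vals <- x$values
  excluded <- list(); params_rows <- list(); sf_rows <- list()
  keep <- character(0)
  out_vals <- vals
  for (p in rownames(vals)) {
    y <- vals[p, ]
    set_frac <- vapply(sets, function(idx) mean(is.finite(y[idx])),
                       numeric(1))
    if (any(set_frac < min_valid_fraction)) {
      excluded[[p]] <- sprintf(
        "quantified in %.0f%% of channels in labeling set %s (need >= %.0f%%)",
        100 * min(set_frac), names(sets)[which.min(set_frac)],
        100 * min_valid_fraction)
      next
    }
    # (a) rough leveling by per-set maxima
    set_max <- vapply(sets, function(idx) max(y[idx], na.rm = TRUE),
                      numeric(1))
    global_max <- max(set_max)
    for (s in names(sets)) y[sets[[s]]] <- y[sets[[s]]] * global_max / set_max[s]
    # (b)/(c) iterate combined fit and per-set scaling
    fit <- NULL
    for (iter in seq_len(n_iterations)) {
      fit <- fit_melting(temps, y)
      if (!fit$diagnostics$converged) break
      sf <- vapply(names(sets), function(s) {
        idx <- sets[[s]]
        fit_scaling_factor(temps[idx], y[idx], fit$params)
      }, numeric(1))
      sf_rows[[length(sf_rows) + 1L]] <- data.frame(
        protein_id = p, iteration = iter,
        labeling_set = as.integer(names(sets)), sf = unname(sf),
        stringsAsFactors = FALSE)
      for (s in names(sets)) y[sets[[s]]] <- y[sets[[s]]] / sf[s]
      if (all(abs(sf - 1) < 1e-6)) break
    }
    if (is.null(fit) || !fit$diagnostics$converged) {
      excluded[[p]] <- "combined melting-curve fit failed"
      next
    }
    keep <- c(keep, p)
    out_vals[p, ] <- y
    params_rows[[length(params_rows) + 1L]] <- data.frame(
      protein_id = p, i_min = fit$params$i_min, i_max = fit$params$i_max,
      tm = fit$params$tm, s = fit$params$s,
      n_params = fit$diagnostics$n_params, rss = fit$diagnostics$rss,
      stringsAsFactors = FALSE)
  }
  excluded_df <- if (length(excluded)) {
    data.frame(protein_id = names(excluded), reason = unlist(excluded),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(protein_id = character(0), reason = character(0))
  }
  list(matrix = intensity_matrix(out_vals[keep, , drop = FALSE], ann),
       params = if (length(params_rows)) do.call(rbind, params_rows) else NULL,
       sf = if (length(sf_rows)) do.call(rbind, sf_rows) else NULL,
       excluded = excluded_df)
}

#' Full three-step temperature-range normalization
#'
#' Chains [normalize_tr_step1()] (within-temperature leveling),
#' [normalize_tr_step2()] (global-melting-curve alignment between
#' temperatures) and [normalize_tr_step3()] (per-protein labeling-set
#' leveling). The output matrix supports both melting-curve fitting and
#' within-(temperature, replicate) compound/vehicle ratio analysis.
#'
#' @param x raw `intensity_matrix` in temperature-range layout.
#' @param config `tpp_config()`.
#' @return list with `matrix` and `report` (class `normalization_report`).
#' @export
normalize_tr <- function(x, config = tpp_config("TR")) {
  s1 <- normalize_tr_step1(x)
  s2 <- normalize_tr_step2(s1$matrix)
  s3 <- normalize_tr_step3(s2$matrix,
                           min_valid_fraction = config$min_valid_fraction)
  report <- structure(list(
    step1_constants = s1$constants,
    reference_samples = s1$reference_samples,
    step2_constants = s2$constants,
    step2_intensity_means = s2$intensity_means,
    global_curve = s2$curve,
    sf = s3$sf, protein_params = s3$params, excluded = s3$excluded),
    class = "normalization_report")
  list(matrix = s3$matrix, report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat(sprintf(
    "normalization report: %d samples leveled, global T_m %.2f degC, %d proteins excluded\n",
    length(x$step1_constants), x$global_curve$tm, nrow(x$excluded)))
  invisible(x)
}

## ---- CCR normalization --------------------------------------------------

#' Normalize a concentration-range matrix
#'
#' Within each labeling set, every sample is scaled so that its median log2
#' fold change against the vehicle (0 nM) channel is zero; intensities are
#' then expressed per protein relative to the mean of its vehicle-channel
#' values at the same assay temperature, so that an unaffected protein sits
#' at relative intensity 1 across the dose series.
#'
#' @param x `intensity_matrix` in concentration-range layout
#'   (`concentration` and `assay_temperature` annotated).
#' @return list with `matrix` (relative intensities) and `constants`.
#' @export
normalize_ccr <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  ann <- x$annotation
  if (all(is.na(ann$concentration)))
    stop("concentration annotations are required for CCR normalization")
  vals <- x$values
  constants <- stats::setNames(rep(1, ncol(vals)), colnames(vals))
  for (set in unique(ann$labeling_set)) {
    idx <- which(ann$labeling_set == set)
    veh <- idx[ann$concentration[idx] == 0]
    if (length(veh) != 1)
      stop("labeling set ", set, " lacks a unique vehicle (0 nM) channel")
    for (j in idx) {
      if (j == veh) next
      shared <- is.finite(vals[, j]) & is.finite(vals[, veh]) &
        vals[, j] > 0 & vals[, veh] > 0
      if (!any(shared)) stop("no shared proteins with the vehicle channel")
      constants[j] <- 2^stats::median(log2(vals[shared, veh] /
                                             vals[shared, j]))
      vals[, j] <- vals[, j] * constants[j]
    }
  }
  # express relative to the per-protein vehicle mean at each assay temperature
  for (at in unique(ann$assay_temperature)) {
    cols <- which(ann$assay_temperature == at)
    veh_cols <- cols[ann$concentration[cols] == 0]
    veh_mean <- rowMeans(vals[, veh_cols, drop = FALSE], na.rm = TRUE)
    vals[, cols] <- vals[, cols, drop = FALSE] / veh_mean
  }
  list(matrix = intensity_matrix(vals, ann), constants = constants)
}
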