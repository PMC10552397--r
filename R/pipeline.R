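run_manifest <- function(config, seed, counts) {
  structure(list(config = unclass(config), seed = seed,
                 timestamp = format(Sys.time(), tz = "UTC"),
                 counts = counts), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run manifest (", x$timestamp, " UTC)\n", sep = "")
  for (k in names(x$counts)) cat(sprintf("  %s: %d\n", k, x$counts[[k]]))
  invisible(x)
}

#' End-to-end temperature-range pipeline
#'
#' Three-step normalization, per-protein melting fits, differential
#' stability/abundance analysis and classification; optionally writes all
#' result tables as TSV. Fully deterministic given the input matrix and
#' configuration.
#'
#' @param x raw `intensity_matrix` in temperature-range layout.
#' @param config `tpp_config()`.
#' @param output_dir directory for TSV outputs; `NULL` skips writing.
#' @return list with `results` (differential table), `report`
#'   (normalization report), `normalized` (matrix) and `manifest`.
#' @export
run_tr_pipeline <- function(x, config = tpp_config("TR"),
                            output_dir = NULL) {
  norm <- tryCatch(normalize_tr(x, config), error = function(e)
    stop("normalization stage: ", conditionMessage(e)))
  results <- tryCatch(
    analyze_differential(norm$matrix, config,
                         shape_params = norm$report$protein_params),
    error = function(e)
      stop("differential stage: ", conditionMessage(e)))
  manifest <- run_manifest(config, config$rng_seed, list(
    proteins_in = nrow(x$values),
    proteins_analyzed = nrow(norm$matrix$values),
    proteins_excluded = nrow(norm$report$excluded),
    proteins_significant = sum(results$significant, na.rm = TRUE)))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- results[setdiff(names(results), "per_temperature")]
    utils::write.table(flat, file.path(output_dir, "differential_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    write_intensity_table(norm$matrix,
                          file.path(output_dir, "normalized_intensities.tsv"),
                          file.path(output_dir, "sample_annotation.tsv"))
    utils::write.table(norm$report$excluded,
                       file.path(output_dir, "excluded_proteins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(norm$report$protein_params)) {
      utils::write.table(norm$report$protein_params,
                         file.path(output_dir, "melting_parameters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(results = results, report = norm$report, normalized = norm$matrix,
       manifest = manifest)
}

#' End-to-end concentration-range pipeline
#'
#' Vehicle-anchored normalization followed by per-protein dose-response
#' fitting at both assay temperatures and responder/mechanism
#' classification.
#'
#' @inheritParams run_tr_pipeline
#' @param x raw `intensity_matrix` in concentration-range layout.
#' @return list with `results` (dose-response table), `normalized` and
#'   `manifest`.
#' @export
run_ccr_pipeline <- function(x, config = tpp_config("CCR"),
                             output_dir = NULL) {
  norm <- tryCatch(normalize_ccr(x), error = function(e)
    stop("normalization stage: ", conditionMessage(e)))
  results <- tryCatch(analyze_dose_response(norm$matrix, config),
                      error = function(e)
                        stop("dose-response stage: ", conditionMessage(e)))
  manifest <- run_manifest(config, config$rng_seed, list(
    proteins_in = nrow(x$values),
    proteins_fit = sum(is.finite(results$pec50)),
    responders = sum(results$direction != "none")))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(results,
                       file.path(output_dir, "dose_response_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    write_intensity_table(norm$matrix,
                          file.path(output_dir, "relative_intensities.tsv"),
                          file.path(output_dir, "sample_annotation.tsv"))
  }
  list(results = results, normalized = norm$matrix, manifest = manifest)
}

#' Volcano-style plot of differential results
#'
#' Significance (-log10 adjusted p) against the chosen effect axis,
#' mirroring the usual distance-score / melting-point-shift / abundance
#' panels.
#'
#' @param results `differential_result` table.
#' @param effect `"distance_score"`, `"delta_tm"` or `"abundance_log2fc"`.
#' @return a ggplot object.
#' @export
plot_volcano <- function(results,
                         effect = c("distance_score", "delta_tm",
                                    "abundance_log2fc")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  effect <- match.arg(effect)
  df <- data.frame(x = results[[effect]],
                   y = -log10(pmax(results$adj_p, .Machine$double.xmin)),
                   significant = results$significant)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = effect, y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Pseudo-R^2 versus pEC50 scatter of dose-response results
#'
#' Point size encodes the pseudo-R^2 (50 degC minus 37 degC) difference:
#' large points are pure stability effects, small points abundance effects.
#'
#' @param results `dose_response_result` table.
#' @param direction restrict to `"positive"` or `"negative"` responders;
#'   `NULL` plots everything.
#' @return a ggplot object.
#' @export
plot_dose_response_summary <- function(results, direction = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- results[is.finite(results$pec50), ]
  if (!is.null(direction)) df <- df[df$direction == direction, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pec50, y = .data$pseudo_r2_50,
                                   size = pmax(.data$r2_difference, 0))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::labs(x = "pEC50", y = "pseudo-R2 (50 degC)",
                  size = "r2 difference") +
    ggplot2::theme_minimal()
}
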