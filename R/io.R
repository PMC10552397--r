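#' TMT 10plex channel labels
#'
#' The ten reporter channels of a TMT 10plex labeling set, in mass order.
#' @return character vector of length 10.
#' @export
tmt10_channels <- function() {
  c("126", "127N", "127C", "128N", "128C",
    "129N", "129C", "130N", "130C", "131")
}

ANNOTATION_COLS <- c("sample_id", "labeling_set", "channel", "temperature",
                     "treatment", "replicate", "concentration",
                     "assay_temperature")

#' Construct a protein-by-sample intensity matrix
#'
#' The single currency of the pipeline: nonnegative reporter-ion intensities
#' for proteins (rows) across annotated samples (columns). Missing values are
#' `NA` and are distinct from zero; a raw zero means a non-detection and is
#' converted to `NA` at load time (see [read_intensity_table()]).
#'
#' @param values numeric matrix, rows = proteins, columns = samples; row
#'   names are protein ids, column names sample ids.
#' @param annotation data frame with one row per sample; columns
#'   `sample_id`, `labeling_set`, `channel`, `temperature`, `treatment`
#'   (`"compound"`/`"vehicle"`), `replicate`, and for
#'   concentration-range data `concentration` (nM) and `assay_temperature`
#'   (degC). Rows are matched to `values` columns by `sample_id`.
#' @return object of class `intensity_matrix`: list with `values` and
#'   `annotation`.
#' @export
intensity_matrix <- function(values, annotation) {
  stopifnot(is.matrix(values), is.data.frame(annotation))
  if (is.null(rownames(values))) stop("values must carry protein row names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids in values")
  needed <- c("sample_id", "labeling_set", "channel", "temperature",
              "treatment", "replicate")
  miss <- setdiff(needed, names(annotation))
  if (length(miss))
    stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(ANNOTATION_COLS, names(annotation)))
    annotation[[col]] <- NA
  annotation <- annotation[ANNOTATION_COLS]
  annotation$sample_id <- as.character(annotation$sample_id)
  annotation$channel <- as.character(annotation$channel)
  annotation$treatment <- as.character(annotation$treatment)
  if (is.null(colnames(values))) colnames(values) <- annotation$sample_id
  if (!identical(sort(colnames(values)), sort(annotation$sample_id)))
    stop("column names of values do not match annotation sample ids")
  annotation <- annotation[match(colnames(values), annotation$sample_id), ]
  rownames(annotation) <- NULL
  if (anyDuplicated(annotation[c("labeling_set", "channel")]))
    stop("(labeling_set, channel) pairs must be unique")
  bad <- !annotation$treatment %in% c("compound", "vehicle") &
    !is.na(annotation$treatment)
  if (any(bad)) stop("treatment must be 'compound' or 'vehicle'")
  if (any(values < 0, na.rm = TRUE)) stop("intensities must be nonnegative")
  structure(list(values = values, annotation = annotation),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  ann <- x$annotation
  cat(sprintf(
    "intensity_matrix: %d proteins x %d samples (%d labeling sets, %d missing values)\n",
    nrow(x$values), ncol(x$values), length(unique(ann$labeling_set)),
    sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Subset an intensity matrix
#'
#' @param x `intensity_matrix`.
#' @param proteins row selector (names, indices or logical); `NULL` keeps all.
#' @param samples column selector applied to sample ids; `NULL` keeps all.
#' @return `intensity_matrix`.
#' @export
subset_matrix <- function(x, proteins = NULL, samples = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  if (!is.null(proteins)) v <- v[proteins, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  ann <- x$annotation[match(colnames(v), x$annotation$sample_id), ]
  intensity_matrix(v, ann)
}

#' Read a wide intensity table plus its sample annotation
#'
#' The intensity table is a TSV with a header row, the first column holding
#' protein ids and the remaining columns one sample each. The annotation TSV
#' is keyed by `sample_id` and must cover every intensity column. Raw zeros
#' are non-detections and become `NA`.
#'
#' @param path intensity TSV path.
#' @param annotation_path annotation TSV path.
#' @return `intensity_matrix`.
#' @export
read_intensity_table <- function(path, annotation_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("intensity table needs an id column and samples")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  values[values == 0] <- NA_real_
  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ann$sample_id <- as.character(ann$sample_id)
  unmatched <- setdiff(colnames(values), ann$sample_id)
  if (length(unmatched))
    stop("no annotation for sample column(s): ",
         paste(unmatched, collapse = ", "))
  ann <- ann[ann$sample_id %in% colnames(values), , drop = FALSE]
  intensity_matrix(values, ann)
}

#' Write an intensity matrix (and its annotation) to TSV
#'
#' Missing values become empty cells, which [read_intensity_table()] reads
#' back as `NA`; the round trip is value-identical.
#'
#' @param x `intensity_matrix`.
#' @param path intensity TSV path.
#' @param annotation_path annotation TSV path; `NULL` to skip.
#' @param id_column name for the protein id column.
#' @return `x`, invisibly.
#' @export
write_intensity_table <- function(x, path, annotation_path = NULL,
                                  id_column = "protein_id") {
  stopifnot(inherits(x, "intensity_matrix"))
  # %.17g is the shortest representation guaranteeing an exact double
  # round trip
  chr <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values),
                dimnames = dimnames(x$values))
  chr[is.na(x$values)] <- NA_character_
  out <- data.frame(rownames(x$values), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1] <- id_column
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  if (!is.null(annotation_path)) {
    utils::write.table(x$annotation, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(x)
}

#' Build the paired-TMT temperature-range sample annotation
#'
#' Treatment and control samples of the same temperature share a TMT 10plex
#' labeling set so that compound/vehicle ratios are within-run; the
#' temperatures are split across two labeling sets per replicate by
#' alternating the descending-sorted list (for the standard ten-temperature
#' grid: set 1 carries 64.0/56.0/49.8/44.0/36.5 degC, set 2 carries
#' 67.0/59.2/53.3/47.1/41.2 degC). Channels are assigned in descending
#' temperature order, vehicle before compound.
#'
#' @param temperatures numeric vector of distinct temperatures (even count).
#' @param replicates number of replicates (>= 1).
#' @return annotation data frame with `2 * length(temperatures) * replicates`
#'   rows and `2 * replicates` labeling sets; sample ids are
#'   `"{set}:{channel}"`.
#' @export
build_tr_design <- function(temperatures, replicates = 3) {
  stopifnot(is.numeric(temperatures), replicates >= 1)
  if (anyDuplicated(temperatures)) stop("temperatures must be distinct")
  if (length(temperatures) %% 2 != 0)
    stop("need an even number of temperatures (two labeling sets)")
  desc <- sort(temperatures, decreasing = TRUE)
  ranks <- seq_along(desc)
  set_two <- desc[ranks %% 2 == 1]   # hottest, 3rd hottest, ...
  set_one <- desc[ranks %% 2 == 0]
  channels <- tmt10_channels()
  half <- length(temperatures) / 2
  if (2 * half > length(channels))
    stop("more than ", length(channels), " channels required per set")
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    for (which_set in 1:2) {
      temps <- if (which_set == 1) set_one else set_two
      set_id <- (rep_i - 1) * 2 + which_set
      k <- 0L
      for (tmp in temps) for (trt in c("vehicle", "compound")) {
        k <- k + 1L
        ch <- channels[k]
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0(set_id, ":", ch),
          labeling_set = set_id, channel = ch, temperature = tmp,
          treatment = trt, replicate = rep_i,
          concentration = NA_real_, assay_temperature = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Build the compound-concentration-range sample annotation
#'
#' One TMT 10plex labeling set per (assay temperature, replicate), one
#' channel per concentration in increasing dose order (vehicle = 0 nM on the
#' first channel).
#'
#' @param concentrations numeric vector of doses in nM including 0; at most
#'   10 values.
#' @param replicates number of replicates.
#' @param assay_temperatures heating temperatures in degC (default 50 with a
#'   37 degC abundance control).
#' @return annotation data frame; `length(concentrations)` samples per set.
#' @export
build_ccr_design <- function(concentrations = make_concentration_series(),
                             replicates = 3,
                             assay_temperatures = c(50, 37)) {
  stopifnot(is.numeric(concentrations), all(concentrations >= 0))
  channels <- tmt10_channels()
  if (length(concentrations) > length(channels))
    stop("at most ", length(channels), " concentrations per labeling set")
  conc <- sort(concentrations)
  rows <- list()
  set_id <- 0L
  for (rep_i in seq_len(replicates)) for (at in assay_temperatures) {
    set_id <- set_id + 1L
    for (k in seq_along(conc)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(set_id, ":", channels[k]),
        labeling_set = set_id, channel = channels[k],
        temperature = at, treatment = if (conc[k] == 0) "vehicle" else "compound",
        replicate = rep_i, concentration = conc[k], assay_temperature = at,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run configuration
#'
#' All thresholds used by the pipelines, with validation.
#'
#' @param mode `"TR"`, `"CCR"` or `"CETSA"`.
#' @param significance_alpha protein-level significance threshold after
#'   Benjamini-Hochberg adjustment.
#' @param per_temperature_alpha uncorrected per-temperature significance
#'   threshold feeding the distance score.
#' @param responder_r2_threshold pseudo-R-squared above which a
#'   dose-response fit counts as a responder.
#' @param r2_difference_threshold pseudo-R-squared (50 degC minus 37 degC)
#'   difference above which a responder is called a pure stability effect.
#' @param min_valid_fraction per-labeling-set fraction of quantified channels
#'   a protein needs in every set to be analyzed.
#' @param rng_seed integer seed for any randomized step.
#' @param fit_tol optimizer parameter tolerance.
#' @return list of class `tpp_config`.
#' @export
tpp_config <- function(mode = c("TR", "CCR", "CETSA"),
                       significance_alpha = 0.05,
                       per_temperature_alpha = 0.05,
                       responder_r2_threshold = 0.8,
                       r2_difference_threshold = 0.4,
                       min_valid_fraction = 0.8,
                       rng_seed = 1L,
                       fit_tol = 1e-8) {
  mode <- match.arg(mode)
  fracs <- c(significance_alpha = significance_alpha,
             per_temperature_alpha = per_temperature_alpha,
             responder_r2_threshold = responder_r2_threshold,
             r2_difference_threshold = r2_difference_threshold,
             min_valid_fraction = min_valid_fraction)
  if (any(fracs <= 0 | fracs >= 1))
    stop("thresholds must lie strictly between 0 and 1")
  structure(list(mode = mode, significance_alpha = significance_alpha,
                 per_temperature_alpha = per_temperature_alpha,
                 responder_r2_threshold = responder_r2_threshold,
                 r2_difference_threshold = r2_difference_threshold,
                 min_valid_fraction = min_valid_fraction,
                 rng_seed = as.integer(rng_seed), fit_tol = fit_tol),
            class = "tpp_config")
}

#' Read/write a flat key-value configuration file
#'
#' Plain text, one `key = value` pair per line, `#` comments allowed.
#'
#' @param path file path.
#' @return for `read_config`, a `tpp_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  args <- list()
  for (k in names(vals)) {
    args[[k]] <- if (k == "mode") vals[[k]] else as.numeric(vals[[k]])
  }
  do.call(tpp_config, args)
}

#' @rdname read_config
#' @param config `tpp_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "tpp_config"))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, "")), path)
  invisible(config)
}
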