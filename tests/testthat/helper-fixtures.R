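# small in-code fixtures shared across test files

toy_grid <- function() make_temperature_grid()

# matrix with known per-protein values over a minimal TR design
toy_tr_matrix <- function(n_proteins = 6, replicates = 1,
                          temperatures = c(40, 50, 55, 60)) {
  design <- build_tr_design(temperatures, replicates)
  set.seed(99)
  vals <- matrix(10^runif(n_proteins * nrow(design), 4, 6),
                 nrow = n_proteins,
                 dimnames = list(sprintf("P%02d", seq_len(n_proteins)),
                                 design$sample_id))
  intensity_matrix(vals, design)
}

# annotation for a single-replicate two-arm series on the standard grid
cetsa_annotation <- function(replicates = 3) {
  expand.grid(temperature = make_temperature_grid(),
              treatment = c("vehicle", "compound"),
              replicate = seq_len(replicates),
              stringsAsFactors = FALSE)
}

# noiseless paired-arm vector for one protein on the full TR design
noiseless_protein <- function(design, params, delta_tm = 0,
                              abundance_log2fc = 0) {
  comp <- design$treatment == "compound"
  y <- numeric(nrow(design))
  y[!comp] <- melting_model(params, design$temperature[!comp])
  shifted <- melting_params(params$i_min * 2^abundance_log2fc,
                            params$i_max * 2^abundance_log2fc,
                            params$tm + delta_tm, params$s)
  y[comp] <- melting_model(shifted, design$temperature[comp])
  names(y) <- design$sample_id
  y
}
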