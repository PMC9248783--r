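# small in-code fixtures shared across test files

# long melt tibble from a named list of RFU vectors on one grid
melt_tbl <- function(series, temps) {
  dplyr::bind_rows(lapply(names(series), function(id) {
    tibble::tibble(sample_id = id, temperature = temps, rfu = series[[id]])
  }))
}

# curves tibble (dneg) from a named list of vectors
curves_tbl <- function(series, temps) {
  dplyr::bind_rows(lapply(names(series), function(id) {
    tibble::tibble(sample_id = id, temperature = temps, dneg = series[[id]])
  }))
}

# noiseless two-state fluorescence series
logistic_f <- function(grid, tm, width = 0.6, b0 = 2, b1 = -0.01, A = 1) {
  b0 + b1 * grid + A / (1 + exp((grid - tm) / width))
}

ramp_grid <- function() seq(65, 95, by = 0.1)

# noiseless melting curve (temperature + dneg tibble) for a planted Tm
logistic_dneg <- function(grid, tm, width = 0.6) {
  mc <- melt_curves(melt_tbl(list(w = logistic_f(grid, tm, width)), grid),
                    smooth = FALSE)
  mc[, c("temperature", "dneg")]
}
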