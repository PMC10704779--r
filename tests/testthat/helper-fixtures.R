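# Shared fixtures, built in code at test time.

zero_noise_config <- function(...) {
  cohort_config(length_noise_sd = 0, weight_lognoise_sd = 0, ...)
}

# long readings table from a named list of per-fish read vectors
readings_from_list <- function(reads, structure = "otolith") {
  purrr::imap_dfr(reads, function(r, id) {
    tibble::tibble(
      fish_id = id, structure = structure,
      read_index = seq_along(r), reading = r
    )
  })
}

# closed-form simple-OLS slope/intercept via the normal equations,
# independent of lm()
normal_equation_line <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# brute-force GLS coefficients via explicit matrix inversion
brute_force_gls <- function(X, y, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)[, 1]
}
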