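# Fast IIR filtering: direct-form-II-transposed b/a application (compiled),
# applied per column with zero initial conditions. Equivalent to
# signal::filter(flt, x).

filter_ba <- function(flt, x) {
  b <- as.numeric(flt$b)
  a <- as.numeric(flt$a)
  if (abs(a[1] - 1) > 1e-15) {
    b <- b / a[1]
    a <- a / a[1]
  }
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  y <- iir_filter_cols(b, a, x)
  if (vec) as.numeric(y) else y
}

# scale every column to unit standard deviation
unit_sd_cols <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sdv <- sqrt((colSums(x^2) - n * mu^2) / (n - 1))
  sweep(x, 2, sdv, "/")
}
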