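#' @importFrom stats coef lm predict qt pt sd setNames var rnorm runif
#' @importFrom utils read.csv write.csv
NULL

# numerically stable log(sum(exp(x))) with optional weights on the linear scale
logsumexp <- function(x, w = NULL) {
  keep <- is.finite(x) | x == -Inf
  if (!all(keep)) stop("non-finite (NaN/+Inf) values in logsumexp")
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  if (is.null(w)) m + log(sum(exp(x - m))) else m + log(sum(w * exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gauss-Legendre nodes/weights on [lo, hi] (cached per (n, lo, hi) call site
# is unnecessary: pracma's computation is cheap at the sizes used here)
gl_nodes <- function(n, lo, hi) {
  if (!(hi > lo)) stop("empty quadrature interval [", lo, ", ", hi, "]")
  g <- pracma::gaussLegendre(n, lo, hi)
  list(x = g$x, w = g$w)
}

stopifnot_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

write_json_plain <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
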