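# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stars_for_p <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

# multiplicative lognormal factors with mean 1 and coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

is_constant_row <- function(x) {
  x <- x[is.finite(x)]
  length(x) == 0L || max(x) - min(x) == 0
}

check_numeric_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must have row and column names", call. = FALSE)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop(what, " has duplicated row or column labels", call. = FALSE)
  invisible(m)
}
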