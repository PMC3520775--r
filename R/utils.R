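#' Rounding helpers matching printed-table conventions
#'
#' `round_half_up()` rounds half away from zero (the convention of the
#' published PK tables, unlike R's banker's rounding); `signif2()` rounds to
#' two significant figures the same way.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname round_half_up
#' @export
signif2 <- function(x) {
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz])))
  out[nz] <- round_half_up(x[nz] / 10^(e - 1)) * 10^(e - 1)
  out
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single finite positive number.", name))
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a single finite non-negative number.", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
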