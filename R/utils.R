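# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounding convention used everywhere a molecule count is produced:
#' 0.5 rounds to 1, -0.5 to -1, unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_away(c(0.4, 0.5, 1.5, 2.5))
#' @export
round_half_away <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

# grams per dalton: inverse Avogadro number, so that one mole of daltons
# weighs exactly one gram
.DA_TO_G <- 1 / 6.0221408e23
# litres per cubic micrometre
.UM3_TO_L <- 1e-15
# angstroms per micrometre
.UM_TO_ANGSTROM <- 1e4

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive number, got %s", name,
                 paste(format(x), collapse = ",")), call. = FALSE)
  }
  invisible(x)
}

.check_fraction <- function(x, name, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) {
    stop(sprintf("'%s' must lie in [0,%s), got %s", name,
                 if (open_right) "1" else "1]", format(x)), call. = FALSE)
  }
  invisible(x)
}
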