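#' Round half away from zero
#'
#' Integer rounding with the "half up" convention used for the percent
#' columns of the event summary tables (e.g. 68.75 -> 69), as opposed to
#' [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set the RNG seed when one is supplied
#'
#' All stochastic functions in the package accept `seed = NULL`; a non-NULL
#' value seeds the session RNG so identical seeds give bit-identical output.
#' @noRd
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

stop_if_not_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s must have columns: %s (missing: %s)",
                 what, paste(cols, collapse = ", "),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
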