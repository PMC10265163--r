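# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 0.5 -> 1, 28.95 -> 29.0), the convention used for the report
#' percentages. Base `round()` rounds half to even, which would print
#' e.g. 0.5 as 0.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector of the same length.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Consistent "is a single non-NA string" check.
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Format doubles for on-disk TSVs so that read-back reproduces the value
# exactly (17 significant digits round-trips IEEE doubles).
format_full <- function(x) sprintf("%.17g", x)
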