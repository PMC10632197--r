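# Shared internal helpers: time handling and rounding.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded up (away from zero),
#' the convention used in clinical tables, rather than R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round(0.125, 2) gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# All timestamps are timezone-naive at minute resolution; internally they are
# POSIXct pinned to UTC so arithmetic is unambiguous.
.tz <- "UTC"

parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(round_minute(x))
  if (length(x) == 0)
    return(as.POSIXct(numeric(0), origin = "1970-01-01", tz = .tz))
  out <- as.POSIXct(x, tz = .tz,
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  round_minute(out)
}

format_time <- function(t) format(t, "%Y-%m-%dT%H:%M", tz = .tz)

round_minute <- function(t) {
  as.POSIXct(round(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = .tz)
}

hours <- function(h) h * 3600

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
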