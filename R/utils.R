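#' @importFrom rlang %||% .data abort warn
#' @importFrom stats sd setNames rbeta rbinom rpois runif rnorm
#' @importFrom utils head tail
NULL

#' Round half away from zero
#'
#' Report tables in this field round halves up (0.645 -> 0.65), unlike base
#' [round()] which rounds half to even. A small epsilon guards against values
#' such as 0.065 that are not exactly representable in binary.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Calendar day in study-local time (default UTC+10, Queensland; no DST) of a
# UTC instant. All day-level statistics are local days.
local_day <- function(time_utc, tz_offset_hours = 10) {
  as.Date(as.POSIXct(time_utc, tz = "UTC") + tz_offset_hours * 3600, tz = "UTC")
}

# local clock hour (0-23) of a UTC instant
local_hour <- function(time_utc, tz_offset_hours = 10) {
  as.integer(format(as.POSIXct(time_utc, tz = "UTC") + tz_offset_hours * 3600,
                    "%H", tz = "UTC"))
}

# 32-bit FNV-1a over a string; used only for run-manifest fingerprints
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor touches only the low byte; split to stay inside 31-bit bitwXor
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, b)
    # 32-bit modular multiply in 16-bit halves (doubles stay exact)
    h <- ((h %% 65536) * p + ((h %/% 65536) * p %% 65536) * 65536) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}
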