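# Clock-time helpers shared by readers, reports and the circular statistics.

#' Parse clock times to decimal hours
#'
#' Accepts `"HH:MM"` (24-h dialect, optionally signed) or plain decimal-hour
#' strings/numerics. `"25:30"`-style values beyond 24 h are allowed so that
#' series spanning midnight can be stored already unwrapped.
#'
#' @param x Character or numeric vector of clock times.
#' @return Numeric vector of decimal hours.
#' @examples
#' parse_clock(c("09:00", "01:30", "23:45"))
#' parse_clock("-00:22")
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- numeric(length(x))
  hm <- grepl(":", x, fixed = TRUE)
  if (any(hm)) {
    sgn <- ifelse(startsWith(x[hm], "-"), -1, 1)
    xs <- sub("^[+-]", "", x[hm])
    parts <- strsplit(xs, ":", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed clock time(s): ", paste(x[hm][bad], collapse = ", "))
    h <- as.numeric(vapply(parts, `[`, "", 1L))
    m <- as.numeric(vapply(parts, `[`, "", 2L))
    if (anyNA(h) || anyNA(m) || any(m < 0 | m >= 60)) {
      stop("malformed clock time(s): ", paste(x[hm], collapse = ", "))
    }
    out[hm] <- sgn * (h + m / 60)
  }
  out[!hm] <- suppressWarnings(as.numeric(x[!hm]))
  if (anyNA(out[!hm]) && !anyNA(x[!hm])) stop("malformed clock time(s)")
  out
}

#' Format decimal hours as HH:MM
#'
#' Negative inputs (signed time differences) keep their sign, e.g. `-0.367`
#' becomes `"-00:22"`. Minutes are rounded to the nearest integer.
#'
#' @param hours Numeric vector of decimal hours.
#' @param wrap If `TRUE`, reduce modulo 24 before formatting (clock-of-day).
#' @return Character vector.
#' @examples
#' format_clock(c(3.9167, 22.8))
#' format_clock(-0.3667)
#' @export
format_clock <- function(hours, wrap = FALSE) {
  if (wrap) hours <- hours %% 24
  sgn <- ifelse(hours < 0, "-", "")
  h <- abs(hours)
  mins <- round(h * 60)
  hh <- mins %/% 60
  mm <- mins %% 60
  sprintf("%s%02d:%02d", sgn, hh, mm)
}

#' Unwrap clock times across midnight
#'
#' Converts a subject's sampling clock times (wrapped to `[0, 24)`) into a
#' strictly increasing sequence of decimal hours since the first-sample
#' midnight by adding 24 h at every backwards step. The 7-draw hormone design
#' 09:00, 13:00, ..., 01:00, 05:00, 09:00 therefore becomes
#' 9, 13, 17, 21, 25, 29, 33.
#'
#' @param hours Numeric vector of clock hours in sampling order.
#' @return Strictly increasing numeric vector.
#' @export
unwrap_times <- function(hours) {
  if (length(hours) == 0L) return(hours)
  out <- hours
  for (i in seq_along(out)[-1]) {
    while (out[i] <= out[i - 1]) out[i] <- out[i] + 24
  }
  out
}

# deterministic sub-seed derivation: one user-facing seed drives several
# independent draw streams without reusing the same state.  Kept below 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + stream * 7919) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a
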