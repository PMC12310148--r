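#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base [round()] rounds half to even; printed compliance percentages follow
#' the conventional half-up rule (86.665 -> 86.67), so summaries use this.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Longest run of TRUE in a logical vector
#'
#' Core primitive for the night rule (longest stretch of consecutive worn
#' minutes inside a sleep period). NAs count as FALSE.
#'
#' @param x logical vector.
#' @return integer, 0 for an empty or all-FALSE vector.
#' @export
longest_run <- function(x) {
  x <- !is.na(x) & x
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# 32-bit FNV-1a over a string; arithmetic kept under 2^53 by 16-bit splits.
fnv1a32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * p) %% 65536) * 65536 + lo * p
    h <- h %% 4294967296
  }
  h
}

# bitwXor for doubles that may exceed .Machine$integer.max
bitwXor_dbl <- function(a, b) {
  hi_a <- floor(a / 2147483648); lo_a <- a - hi_a * 2147483648
  hi_b <- floor(b / 2147483648); lo_b <- b - hi_b * 2147483648
  xor_lo <- bitwXor(as.integer(lo_a), as.integer(lo_b))
  xor_hi <- (hi_a + hi_b) %% 2
  xor_hi * 2147483648 + xor_lo
}

#' Derive a reproducible substream seed
#'
#' Hashes the master seed together with arbitrary labels (group, participant
#' index, ...) so each participant gets an independent stream regardless of
#' the order in which the cohort is generated. Result is a valid
#' [set.seed()] value below 2^31.
#'
#' @param seed master integer seed.
#' @param ... labels folded into the hash.
#' @return integer in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, ...) {
  as.integer(fnv1a32(paste(seed, ..., sep = "|")) %% 2147483647)
}

# Evaluate expr under a temporary RNG state; global .Random.seed restored.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## -- time helpers -----------------------------------------------------------
## Instants are POSIXct in UTC; calendar-day logic applies a fixed
## per-participant offset (minutes), so day boundaries are reproducible and
## DST never enters.

local_date <- function(t, tz_offset_minutes = 0) {
  as.Date(t + tz_offset_minutes * 60, tz = "UTC")
}

# minute-of-day in local time, 0..1439
local_mod <- function(t, tz_offset_minutes = 0) {
  tl <- t + tz_offset_minutes * 60
  as.integer(format(tl, "%H", tz = "UTC")) * 60L +
    as.integer(format(tl, "%M", tz = "UTC"))
}

iso_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_iso_utc <- function(s) {
  as.POSIXct(sub("Z$", "", s), format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# local wall-clock (date, "HH:MM:SS") -> UTC instant
local_to_utc <- function(date_str, time_str, tz_offset_minutes = 0) {
  as.POSIXct(paste(date_str, time_str), tz = "UTC") - tz_offset_minutes * 60
}

floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

stopifnot_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
}
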