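# Month, day-boundary and seed utilities shared across the package.
#
# Calendar months are held internally as an integer index ym = 12*year +
# (month - 1) so that backdating and spans are plain arithmetic; user-facing
# functions accept and return "YYYY-MM" strings, Date, or the integer form.

ym <- function(year, month) {
  stopifnot(all(month >= 1L & month <= 12L))
  as.integer(year) * 12L + (as.integer(month) - 1L)
}

ym_year <- function(x) x %/% 12L
ym_month <- function(x) x %% 12L + 1L

ym_parse <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  if (inherits(x, "Date") || inherits(x, "POSIXt")) {
    lt <- as.POSIXlt(x, tz = "UTC")
    return(ym(lt$year + 1900L, lt$mon + 1L))
  }
  m <- regmatches(x, regexec("^([0-9]{4})-([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("month must be 'YYYY-MM', a Date, or a month index: ", x[bad][1])
  yr <- as.integer(vapply(m, `[`, "", 2L))
  mo <- as.integer(vapply(m, `[`, "", 3L))
  if (any(mo < 1L | mo > 12L)) stop("month number out of 1..12")
  ym(yr, mo)
}

ym_format <- function(x) sprintf("%04d-%02d", ym_year(x), ym_month(x))

#' First instant (UTC) of a calendar month
#' @noRd
ym_start <- function(x) {
  as.POSIXct(sprintf("%04d-%02d-01 00:00:00", ym_year(x), ym_month(x)), tz = "UTC")
}

#' Number of days in a calendar month
#' @noRd
ym_ndays <- function(x) {
  as.numeric(difftime(ym_start(x + 1L), ym_start(x), units = "days"))
}

#' Civil-day index of a timestamp under a fixed UTC offset
#'
#' The study system runs on UTC+2 civil time; daily means change with the
#' day boundary, so the offset is explicit everywhere.
#' @noRd
civil_day <- function(t, tz_offset_h = 2) {
  as.Date(floor((as.numeric(t) + tz_offset_h * 3600) / 86400), origin = "1970-01-01")
}

#' Calendar month ("YYYY-MM" index) of a timestamp under a fixed UTC offset
#' @noRd
civil_ym <- function(t, tz_offset_h = 2) {
  lt <- as.POSIXlt(as.numeric(t) + tz_offset_h * 3600, tz = "UTC",
                   origin = "1970-01-01")
  ym(lt$year + 1900L, lt$mon + 1L)
}

#' Evaluate an expression under a given RNG seed, restoring the prior state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Stable per-female seed stream derived from a master seed
#'
#' Polynomial string hash mod a Mersenne prime, so the stream for a female
#' does not depend on iteration order or on how many females are simulated.
#' @noRd
derive_seed <- function(master, id) {
  p <- 2147483647
  h <- 0
  for (cc in utf8ToInt(as.character(id))) h <- (h * 131 + cc) %% p
  as.integer((as.numeric(master) %% p * 2654435 + h) %% p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
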