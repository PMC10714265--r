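# Internal utilities: timestamp handling, rounding, interval algebra.
# All instants are POSIXct in UTC; all intervals are half-open [start, end).

#' @import data.table
#' @importFrom stats rbinom rgamma rlnorm rnorm rexp runif sd setNames rpois
#' @importFrom utils head tail
NULL

# Parse ISO-8601 timestamps with an explicit offset ("2021-01-20T09:00:00+0000",
# "...+00:00" or "...Z") into POSIXct normalized to UTC.  Returns NA for
# unparseable input; callers decide whether that is fatal.
parse_ts <- function(x) {
  x <- as.character(x)
  x <- sub("Z$", "+0000", x)
  # tolerate "+hh:mm" offsets, which strptime's %z does not accept
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
  out
}

format_ts <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC")
}

# floor a POSIXct to whole seconds (serialization carries second precision,
# so generated data is kept on the integer-second grid)
floor_sec <- function(t) {
  as.POSIXct(floor(as.numeric(t)), origin = "1970-01-01", tz = "UTC")
}

#' Round half-up at a fixed number of decimal digits
#'
#' Base `round()` uses round-half-to-even; report percentages use the
#' conventional half-up rule (0.125 -> 0.13 at 2 digits).
#'
#' @param x numeric vector
#' @param digits number of decimal digits (>= 0)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Truncate (round toward zero) at fixed decimal digits; small epsilon guards
# against 29.21 stored as 29.20999... flooring one ulp short.
trunc_at <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 1e-9) / p
}

#' Merge a set of half-open intervals into their disjoint union
#'
#' @param start,end numeric or POSIXct vectors of equal length; each pair is an
#'   interval `[start, end)`.  Zero-length and reversed intervals are dropped.
#' @return a `data.table` with columns `start`, `end`, sorted, pairwise disjoint
#' @export
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  keep <- !is.na(start) & !is.na(end) & end > start
  start <- start[keep]; end <- end[keep]
  if (length(start) == 0L)
    return(data.table(start = start, end = end))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  run_end <- cummax(as.numeric(end))
  # a new run begins where the interval starts after everything seen so far
  new_run <- c(TRUE, as.numeric(start[-1]) > run_end[-length(run_end)])
  grp <- cumsum(new_run)
  dt <- data.table(start = start, end = end, grp = grp)
  out <- dt[, .(start = min(start), end = max(end)), by = grp][, grp := NULL]
  out[]
}

# Total length of the union of [start, end) intervals, in seconds.
interval_union_seconds <- function(start, end) {
  m <- merge_intervals(start, end)
  if (nrow(m) == 0L) return(0)
  sum(as.numeric(m$end) - as.numeric(m$start))
}

# Deterministic 31-bit seed derived from a base seed and a string id, so each
# interviewer owns an independent reproducible stream.
derive_seed <- function(seed, id) {
  h <- 0
  for (b in utf8ToInt(as.character(id))) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fwrite wrapper fixing dialect options so serialization is byte-stable.
qc_fwrite <- function(dt, path) {
  data.table::fwrite(dt, path, sep = ",", quote = TRUE, eol = "\n",
                     na = "", logical01 = FALSE, scipen = 50)
  invisible(path)
}

qc_fread <- function(path, colClasses = NULL) {
  data.table::fread(path, sep = ",", header = TRUE, na.strings = "",
                    colClasses = colClasses, data.table = TRUE)
}

abort_row <- function(msg, file = NULL, row = NULL) {
  loc <- if (!is.null(file)) sprintf(" [%s%s]", basename(file),
                                     if (!is.null(row)) paste0(":", row) else "")
         else ""
  stop(sprintf("%s%s", msg, loc), call. = FALSE)
}
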