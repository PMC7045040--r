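#' Weekday levels used throughout the package
#'
#' Days are handled as a cyclic factor Mon..Sun. Sunday is the reference
#' level for dummy coding, so weekday effects are interpreted as deviations
#' from Sunday.
#'
#' @format Character vector of length 7.
#' @export
WEEKDAYS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

weekday_index <- function(weekday) {
  idx <- match(weekday, WEEKDAYS)
  if (anyNA(idx)) {
    stop_memlag(sprintf("invalid weekday value(s): %s",
                        paste(unique(weekday[is.na(idx)]), collapse = ", ")),
                "memlag_invalid_weekday")
  }
  idx
}

#' Cyclic weekday sequence
#'
#' @param start Weekday of the first day (one of `WEEKDAYS`).
#' @param n Length of the sequence.
#' @return Character vector of `n` weekday labels advancing cyclically.
#' @export
weekday_sequence <- function(start, n) {
  s <- weekday_index(start)
  WEEKDAYS[((s - 1L + seq_len(n) - 1L) %% 7L) + 1L]
}

#' Dummy-code weekdays with Sunday as the reference
#'
#' Returns one indicator column per non-reference day (`d_mon` .. `d_sat`);
#' a Sunday row is all zero.
#'
#' @param weekday Character vector of weekday labels.
#' @return Numeric matrix with 6 columns.
#' @examples
#' encode_weekday(c("Sun", "Mon", "Sat"))
#' @export
encode_weekday <- function(weekday) {
  idx <- weekday_index(weekday)
  m <- matrix(0, nrow = length(idx), ncol = 6L,
              dimnames = list(NULL, paste0("d_", tolower(WEEKDAYS[1:6]))))
  keep <- idx <= 6L
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

# classed errors so callers/tests can distinguish failure modes
stop_memlag <- function(message, class) {
  stop(structure(class = c(class, "memlag_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}
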