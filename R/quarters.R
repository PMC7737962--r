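#' Calendar-quarter utilities
#'
#' Quarters are handled internally as an integer index `year * 4 +
#' (quarter - 1)`, so consecutive quarters differ by exactly 1 and
#' arithmetic on trends ("percentage points per annual quarter") is exact.
#' The external label format is `"1998Q1"`.
#'
#' @param x character vector of quarter labels such as `"2002Q4"`, or an
#'   integer index vector (returned unchanged).
#' @return `quarter_index()` returns an integer vector; `quarter_label()`
#'   the `"YYYYQq"` labels; `quarter_start()`/`quarter_midpoint()` `Date`s.
#' @examples
#' quarter_index("1998Q1")
#' quarter_label(quarter_index("1998Q1") + 1)
#' @name quarters
NULL

#' @rdname quarters
#' @export
quarter_index <- function(x) {
  if (is.numeric(x)) {
    return(as.integer(x))
  }
  m <- regmatches(x, regexec("^([0-9]{4})Q([1-4])$", x))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop("malformed quarter label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  vapply(m, function(p) as.integer(p[2]) * 4L + as.integer(p[3]) - 1L, integer(1))
}

#' @rdname quarters
#' @export
quarter_label <- function(x) {
  x <- as.integer(x)
  sprintf("%dQ%d", x %/% 4L, x %% 4L + 1L)
}

#' @rdname quarters
#' @export
quarter_year <- function(x) quarter_index(x) %/% 4L

#' @rdname quarters
#' @export
quarter_start <- function(x) {
  x <- quarter_index(x)
  as.Date(sprintf("%d-%02d-01", x %/% 4L, (x %% 4L) * 3L + 1L))
}

#' @rdname quarters
#' @export
quarter_midpoint <- function(x) {
  # day 45 of the quarter; with +/-40 days of jitter a date stays inside
  # its quarter (the shortest quarter, Q1, has 90 days)
  quarter_start(x) + 44L
}

#' Quarter containing a date
#'
#' @param date a `Date` vector.
#' @return integer quarter index (see [quarter_index()]).
#' @export
date_quarter <- function(date) {
  lt <- as.POSIXlt(date)
  (lt$year + 1900L) * 4L + lt$mon %/% 3L
}

#' Era of a quarter relative to three data-collection change points
#'
#' Identifier-collection practice changed three times (NN4B at birth
#' notification, the RON registration system, and the correction of the
#' birth-postcode extraction error). `era_of()` maps each quarter to the
#' period it falls in: era 0 strictly before the first change point, and
#' era k from the k-th change point (inclusive) onwards.
#'
#' @param quarter quarter labels or indices.
#' @param change_points three strictly increasing quarter labels/indices;
#'   defaults to `c("2002Q4", "2009Q3", "2013Q2")`.
#' @return integer vector of eras in `0:3`.
#' @examples
#' era_of(c("2002Q3", "2002Q4", "2013Q2"))
#' @export
era_of <- function(quarter, change_points = c("2002Q4", "2009Q3", "2013Q2")) {
  cp <- quarter_index(change_points)
  if (length(cp) != 3L || is.unsorted(cp, strictly = TRUE)) {
    stop("change_points must be three strictly increasing quarters")
  }
  q <- quarter_index(quarter)
  findInterval(q, cp)
}
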