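#' Epidemiological week labels
#'
#' Weekly series are indexed by epidemiological week labels of the form
#' `"YYYY-Www"` (e.g. `"2009-W11"`). A year carries 52 or 53 weeks following
#' the ISO-8601 week count; consecutive means +1 week with year rollover.
#'
#' @param labels character vector of `"YYYY-Www"` labels.
#' @return `parse_week()` returns a data.frame with integer `year` and `week`.
#' @examples
#' parse_week("2009-W11")
#' week_seq("2009-W50", 5)
#' @export
parse_week <- function(labels) {
  m <- regmatches(labels, regexec("^([0-9]{4})-W([0-9]{2})$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("invalid week label(s): ", paste(labels[bad], collapse = ", "),
         " (expected \"YYYY-Www\")")
  }
  year <- vapply(m, function(x) as.integer(x[2]), 1L)
  week <- vapply(m, function(x) as.integer(x[3]), 1L)
  nw <- weeks_in_year(year)
  out <- week < 1L | week > nw
  if (any(out)) {
    stop("week number out of range in label(s): ",
         paste(labels[out], collapse = ", "))
  }
  data.frame(year = year, week = week)
}

#' @rdname parse_week
#' @param year integer vector of calendar years.
#' @return `weeks_in_year()` returns 52 or 53 per year.
#' @export
weeks_in_year <- function(year) {
  # ISO-8601: Dec 28 always falls in the last week of its week-year
  as.integer(strftime(as.Date(paste0(year, "-12-28")), "%V"))
}

format_week <- function(year, week) {
  sprintf("%04d-W%02d", year, week)
}

next_week <- function(label) {
  p <- parse_week(label)
  if (p$week < weeks_in_year(p$year)) {
    format_week(p$year, p$week + 1L)
  } else {
    format_week(p$year + 1L, 1L)
  }
}

#' @rdname parse_week
#' @param start first week label.
#' @param n number of consecutive weeks.
#' @return `week_seq()` returns `n` consecutive labels starting at `start`.
#' @export
week_seq <- function(start, n) {
  stopifnot(n >= 1)
  out <- character(n)
  out[1] <- start
  parse_week(start) # validate
  if (n > 1) for (i in 2:n) out[i] <- next_week(out[i - 1])
  out
}

# error (naming the offending label) unless labels are strictly consecutive
check_consecutive <- function(labels, what = "week") {
  if (anyDuplicated(labels)) {
    stop("duplicated ", what, " label: ",
         labels[duplicated(labels)][1])
  }
  if (length(labels) > 1) {
    for (i in 2:length(labels)) {
      if (labels[i] != next_week(labels[i - 1])) {
        stop("weeks not consecutive at ", labels[i],
             " (expected ", next_week(labels[i - 1]),
             " after ", labels[i - 1], ")")
      }
    }
  }
  invisible(labels)
}
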