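#' Weekly entomological and meteorological series
#'
#' An `entomo_series` holds one row per epidemiological week of a sticky-trap
#' surveillance programme: the total number of adult female mosquitoes
#' captured (`total_captures`), the number of traps with at least one capture
#' (`positive_traps`) and the number of traps inspected (`observed_traps`).
#' Two denominators coexist deliberately: `positive_traps` is the denominator
#' of the per-trap abundance (the autoregressive term of the count model),
#' while `observed_traps` enters the model offset `log(observed_traps)` that
#' corrects for variable sampling effort.
#'
#' A `meteo_series` holds the eight weekly meteorological covariates:
#' accumulated precipitation (mm), minimum/average/maximum temperature
#' (degrees C), minimum/average/maximum relative humidity (%) and wind speed
#' (m/s), with the per-week orderings tmin <= tavg <= tmax and
#' hmin <= havg <= hmax enforced.
#'
#' @param week character vector of `"YYYY-Www"` labels, strictly consecutive.
#' @param total_captures non-negative integer counts of females per week.
#' @param positive_traps integer, `1 <= positive_traps <= observed_traps`.
#' @param observed_traps positive integer trap-inspection counts.
#' @return a validated data.frame of class `entomo_series`.
#' @seealso [read_entomo()], [capture_rate()], [align_weekly()]
#' @export
entomo_series <- function(week, total_captures, positive_traps,
                          observed_traps) {
  d <- data.frame(week = as.character(week),
                  total_captures = total_captures,
                  positive_traps = positive_traps,
                  observed_traps = observed_traps,
                  stringsAsFactors = FALSE)
  validate_entomo(d)
}

validate_entomo <- function(d) {
  req <- c("week", "total_captures", "positive_traps", "observed_traps")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- d[, req]
  for (f in req[-1]) {
    v <- d[[f]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
      bad <- which(!is.finite(v) | v != round(v))[1]
      stop("non-integer value in field '", f, "' at row ", bad,
           " (week ", d$week[bad], ")")
    }
    d[[f]] <- as.integer(round(v))
  }
  if (any(d$total_captures < 0)) {
    i <- which(d$total_captures < 0)[1]
    stop("negative total_captures at week ", d$week[i])
  }
  if (any(d$positive_traps < 1)) {
    i <- which(d$positive_traps < 1)[1]
    stop("positive_traps < 1 at week ", d$week[i])
  }
  if (any(d$positive_traps > d$observed_traps)) {
    i <- which(d$positive_traps > d$observed_traps)[1]
    stop("positive_traps exceeds observed_traps at week ", d$week[i],
         " (field 'positive_traps')")
  }
  if (nrow(d) < 6) stop("entomological series must have >= 6 weeks")
  check_consecutive(d$week)
  rownames(d) <- NULL
  class(d) <- c("entomo_series", "data.frame")
  d
}

meteo_cols <- c("precip_mm", "tmin_c", "tavg_c", "tmax_c",
                "hmin_pct", "havg_pct", "hmax_pct", "wind_ms")

# short covariate names used by model specifications -> file/data columns
meteo_vars <- c(precip = "precip_mm", tmin = "tmin_c", tavg = "tavg_c",
                tmax = "tmax_c", hmin = "hmin_pct", havg = "havg_pct",
                hmax = "hmax_pct", wind = "wind_ms")

#' @rdname entomo_series
#' @param precip_mm,wind_ms non-negative weekly precipitation and wind speed.
#' @param tmin_c,tavg_c,tmax_c weekly temperature summaries (degrees C).
#' @param hmin_pct,havg_pct,hmax_pct weekly relative humidity in `[0, 100]`.
#' @export
meteo_series <- function(week, precip_mm, tmin_c, tavg_c, tmax_c,
                         hmin_pct, havg_pct, hmax_pct, wind_ms) {
  d <- data.frame(week = as.character(week), precip_mm = precip_mm,
                  tmin_c = tmin_c, tavg_c = tavg_c, tmax_c = tmax_c,
                  hmin_pct = hmin_pct, havg_pct = havg_pct,
                  hmax_pct = hmax_pct, wind_ms = wind_ms,
                  stringsAsFactors = FALSE)
  validate_meteo(d)
}

validate_meteo <- function(d) {
  req <- c("week", meteo_cols)
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- d[, req]
  for (f in meteo_cols) {
    if (!is.numeric(d[[f]]) || any(!is.finite(d[[f]]))) {
      stop("non-numeric or missing value in field '", f, "'")
    }
  }
  stop_at <- function(cond, msg) {
    if (any(cond)) stop(msg, " at week ", d$week[which(cond)[1]])
  }
  stop_at(d$precip_mm < 0, "negative precipitation (field 'precip_mm')")
  stop_at(d$wind_ms < 0, "negative wind speed (field 'wind_ms')")
  stop_at(d$tmin_c > d$tavg_c | d$tavg_c > d$tmax_c,
          "temperature ordering tmin <= tavg <= tmax violated")
  stop_at(d$hmin_pct > d$havg_pct | d$havg_pct > d$hmax_pct,
          "humidity ordering hmin <= havg <= hmax violated")
  stop_at(d$hmin_pct < 0 | d$hmax_pct > 100,
          "relative humidity outside [0, 100]")
  check_consecutive(d$week)
  rownames(d) <- NULL
  class(d) <- c("meteo_series", "data.frame")
  d
}

#' Read and write weekly surveillance tables
#'
#' Comma-delimited text with a header row. Entomological columns:
#' `week,total_captures,positive_traps,observed_traps`. Meteorological
#' columns: `week,precip_mm,tmin_c,tavg_c,tmax_c,hmin_pct,havg_pct,hmax_pct,
#' wind_ms`. Reading validates all series invariants and errors naming the
#' offending row and field; `read_*` after `write_*` is the identity.
#'
#' @param path file path.
#' @return `read_entomo()` an `entomo_series`; `read_meteo()` a
#'   `meteo_series`.
#' @export
read_entomo <- function(path) {
  validate_entomo(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_entomo
#' @export
read_meteo <- function(path) {
  validate_meteo(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_entomo
#' @param x an `entomo_series` / `meteo_series`.
#' @export
write_entomo <- function(x, path) {
  stopifnot(inherits(x, "entomo_series"))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_entomo
#' @export
write_meteo <- function(x, path) {
  stopifnot(inherits(x, "meteo_series"))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-trap capture rate
#'
#' Weekly mean capture rate per positive trap,
#' `a_t = total_captures_t / positive_traps_t`, the entomological index the
#' count model uses as its autoregressive term.
#'
#' @param e an `entomo_series`.
#' @return numeric vector, same length as the series.
#' @export
capture_rate <- function(e) {
  stopifnot(inherits(e, "entomo_series"))
  e$total_captures / e$positive_traps
}

#' Lag a weekly series
#'
#' Shifts a series by `lag` weeks so that element `t` of the output equals
#' element `t - lag` of the input; the first `lag` entries are `NA`
#' (unavailable). Lags up to 4 weeks are supported, matching the adult
#' mosquito lifespan of roughly 2-4 weeks that motivates the lag window.
#'
#' @param x numeric vector.
#' @param lag integer in `0..4`.
#' @return numeric vector of the same length with `lag` leading `NA`s.
#' @examples
#' lagged(c(1, 2, 3), 1)
#' @export
lagged <- function(x, lag) {
  if (length(lag) != 1 || is.na(lag) || lag != round(lag) ||
      lag < 0 || lag > 4) {
    stop("lag must be a single integer in 0..4")
  }
  lag <- as.integer(lag)
  if (length(x) <= lag) stop("series length must exceed lag")
  if (lag == 0) return(x)
  c(rep(NA_real_, lag), x[seq_len(length(x) - lag)])
}

#' Join entomological and meteorological series on the week axis
#'
#' Inner-joins the two tables on `week`, requires the joined axis to be
#' gap-free, and derives the per-trap abundance `abundance = capture_rate()`.
#'
#' @param entomo an `entomo_series`.
#' @param meteo a `meteo_series` covering (at least) the same weeks.
#' @return a data.frame of class `aedes_dataset` with both tables' columns
#'   plus `abundance`.
#' @export
align_weekly <- function(entomo, meteo) {
  stopifnot(inherits(entomo, "entomo_series"), inherits(meteo, "meteo_series"))
  common <- intersect(entomo$week, meteo$week)
  if (length(common) < 6) {
    stop("fewer than 6 weeks shared between entomological and ",
         "meteorological series")
  }
  e <- entomo[entomo$week %in% common, ]
  m <- meteo[meteo$week %in% common, ]
  check_consecutive(common)
  d <- cbind(e, m[match(e$week, m$week), meteo_cols])
  d$abundance <- capture_rate(e)
  rownames(d) <- NULL
  class(d) <- c("aedes_dataset", "data.frame")
  d
}

#' Summary statistics of an aligned weekly dataset
#'
#' Means, ranges and sample variances of the capture counts, per-trap
#' abundance and each meteorological covariate, plus the number of rain-free
#' weeks.
#'
#' @param d an `aedes_dataset` from [align_weekly()].
#' @return a named list of statistics (see examples); `counts$mean` is
#'   `sum/length` and variances are sample variances.
#' @export
summarize_weekly <- function(d) {
  stopifnot(inherits(d, "aedes_dataset"))
  stats_of <- function(x) {
    list(mean = mean(x), min = min(x), max = max(x),
         var = if (length(x) > 1) stats::var(x) else 0)
  }
  covs <- lapply(meteo_cols, function(cl) stats_of(d[[cl]]))
  names(covs) <- meteo_cols
  list(n_weeks = nrow(d),
       counts = stats_of(d$total_captures),
       total_captured = sum(d$total_captures),
       abundance = stats_of(d$abundance),
       covariates = covs,
       zero_rain_weeks = sum(d$precip_mm == 0))
}
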