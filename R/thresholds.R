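# Interaction sign-change thresholds and (T, H) population-growth regions.
#
# With linear predictor b_T*T + b_H*H + b_int*T*H (+ b_ar*a), the partial
# effect of temperature is b_T + b_int*H: it flips sign at the humidity
# h* = -b_T/b_int, and symmetrically the humidity effect flips at
# t* = -b_H/b_int. The growth comparison is made per trap, so the
# log(observed_traps) offset cancels.

growth_coefs <- function(fit) {
  if (inherits(fit, "nbfit")) {
    r <- fit$roles
    if (is.null(r$temp) || is.null(r$hum) || is.null(r$inter) || is.null(r$ar)) {
      stop("fit must contain temperature, humidity, interaction and AR terms")
    }
    b <- fit$coefficients$estimate
    names(b) <- fit$coefficients$term
    list(beta_ar = unname(b[r$ar]), beta_temp = unname(b[r$temp]),
         beta_hum = unname(b[r$hum]), beta_int = unname(b[r$inter]))
  } else {
    stopifnot(is.list(fit),
              all(c("beta_ar", "beta_temp", "beta_hum", "beta_int") %in%
                    names(fit)))
    fit[c("beta_ar", "beta_temp", "beta_hum", "beta_int")]
  }
}

#' Sign-change thresholds of the temperature-humidity interaction
#'
#' @param fit an `nbfit` containing temperature, humidity and interaction
#'   coefficients, or a plain list with `beta_ar`, `beta_temp`, `beta_hum`,
#'   `beta_int`.
#' @return list of class `threshold_pair`: `h_star` (humidity % where the
#'   temperature effect changes sign, `-beta_temp/beta_int`) and `t_star`
#'   (temperature degrees C where the humidity effect changes sign,
#'   `-beta_hum/beta_int`).
#' @examples
#' sign_change_thresholds(list(beta_ar = 0.8344, beta_temp = -0.0714,
#'                             beta_hum = -0.0257, beta_int = 0.0016))
#' @export
sign_change_thresholds <- function(fit) {
  b <- growth_coefs(fit)
  if (b$beta_int == 0) {
    stop("interaction coefficient is zero: sign-change thresholds undefined")
  }
  structure(list(h_star = -b$beta_temp / b$beta_int,
                 t_star = -b$beta_hum / b$beta_int),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  # reported to 1 decimal place, the precision of the derived quantities
  cat(sprintf("temperature effect changes sign at humidity %.1f%%\n", x$h_star))
  cat(sprintf("humidity effect changes sign at temperature %.1f C\n", x$t_star))
  invisible(x)
}

#' Predicted positive population growth at given conditions
#'
#' The population is predicted to grow when the model's expected per-trap
#' abundance exceeds the previous week's abundance:
#' `exp(beta_ar*y_prev + beta_temp*T + beta_hum*H + beta_int*T*H) > y_prev`.
#' The trap-effort offset cancels in the per-trap comparison.
#'
#' @param fit an `nbfit` or coefficient list (see
#'   [sign_change_thresholds()]).
#' @param y_prev previous week's per-trap abundance (> 0).
#' @param temp,hum temperature (degrees C) and relative humidity (%);
#'   vectorized.
#' @return logical vector.
#' @export
growth_condition <- function(fit, y_prev, temp, hum) {
  stopifnot(y_prev > 0)
  b <- growth_coefs(fit)
  eta <- b$beta_ar * y_prev + b$beta_temp * temp + b$beta_hum * hum +
    b$beta_int * temp * hum
  exp(eta) > y_prev
}

#' Growth region over a temperature-humidity grid
#'
#' Evaluates [growth_condition()] on a regular grid and extracts, per
#' temperature, the frontier: the least humidity at which growth is
#' predicted (`NA` where none). The default grid covers the observed
#' meteorological ranges with visible frontier resolution.
#'
#' @inheritParams growth_condition
#' @param t_range,h_range grid ranges (degrees C, %).
#' @param t_step,h_step grid steps.
#' @return a list of class `growth_map`: `temp`, `hum` (grid axes),
#'   `growth` (logical matrix, temperatures in rows), `frontier` (per-
#'   temperature minimal humidity for growth), `y_prev`.
#' @export
growth_map <- function(fit, y_prev, t_range = c(10, 32), h_range = c(30, 100),
                       t_step = 0.1, h_step = 0.5) {
  stopifnot(length(t_range) == 2, length(h_range) == 2,
            t_range[1] <= t_range[2], h_range[1] <= h_range[2],
            t_step > 0, h_step > 0)
  tt <- seq(t_range[1], t_range[2], by = t_step)
  hh <- seq(h_range[1], h_range[2], by = h_step)
  g <- outer(tt, hh, function(a, b) growth_condition(fit, y_prev, a, b))
  frontier <- apply(g, 1, function(row) {
    i <- which(row)[1]
    if (is.na(i)) NA_real_ else hh[i]
  })
  structure(list(temp = tt, hum = hh, growth = g, frontier = frontier,
                 y_prev = y_prev),
            class = "growth_map")
}

#' Serialize a growth map
#'
#' Writes the boolean growth matrix as a CSV (temperature rows, humidity
#' columns, axis headers) and a JSON sidecar with the scenario abundance,
#' sign-change thresholds and frontier curve.
#'
#' @param gm a [growth_map()].
#' @param fit the coefficients the map came from (for the thresholds).
#' @param csv_path,json_path output paths.
#' @export
write_growth_map <- function(gm, fit, csv_path, json_path) {
  stopifnot(inherits(gm, "growth_map"))
  m <- as.data.frame(gm$growth * 1L)
  names(m) <- sprintf("h_%g", gm$hum)
  m <- cbind(data.frame(temp_c = gm$temp), m)
  utils::write.csv(m, csv_path, row.names = FALSE, quote = FALSE)
  th <- sign_change_thresholds(fit)
  jsonlite::write_json(
    list(y_prev = gm$y_prev,
         h_star = round(th$h_star, 1), t_star = round(th$t_star, 1),
         frontier = data.frame(temp_c = gm$temp, min_hum_pct = gm$frontier)),
    json_path, auto_unbox = TRUE, digits = 8, na = "null", pretty = TRUE)
  invisible(csv_path)
}
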