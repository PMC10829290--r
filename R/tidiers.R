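#' Tidiers for fitted objects
#'
#' Broom-style methods: `tidy()` returns one row per estimated term,
#' `glance()` one row of model-level summaries.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name preyscape_tidiers
NULL

#' @rdname preyscape_tidiers
#' @export
tidy.habitat_fit <- function(x, ...) {
  x$coefs
}

#' @rdname preyscape_tidiers
#' @export
glance.habitat_fit <- function(x, ...) {
  tibble::tibble(
    model = x$label, r_squared = x$r2, aic = x$aic,
    ranef_var = x$ranef_var, resid_var = x$resid_var,
    ranef_share = x$ranef_share, n_obs = x$n_obs, n_groups = x$n_groups
  )
}

#' @rdname preyscape_tidiers
#' @export
tidy.variogram_fit <- function(x, ...) {
  tibble::tibble(
    term = c("nugget", "partial_sill", "range_param", "effective_range"),
    estimate = c(x$nugget, x$partial_sill, x$range_param,
                 x$effective_range_m)
  )
}

#' @rdname preyscape_tidiers
#' @export
glance.variogram_fit <- function(x, ...) {
  tibble::tibble(
    effective_range_m = x$effective_range_m,
    nugget = x$nugget, partial_sill = x$partial_sill,
    range_identifiable = x$range_identifiable,
    n_lags = nrow(x$empirical)
  )
}

#' @rdname preyscape_tidiers
#' @export
tidy.ud_surface <- function(x, ...) {
  dplyr::mutate(x$isopleths, bandwidth_x = x$bandwidth[1],
                bandwidth_y = x$bandwidth[2])
}

#' @rdname preyscape_tidiers
#' @export
tidy.ud_volume <- function(x, ...) {
  dplyr::mutate(x$isopleths, period = x$period)
}

#' @rdname preyscape_tidiers
#' @export
tidy.ts_result <- function(x, ...) {
  tibble::tibble(length_m = x$config$lengths_m, sigma_bs = x$sigma_bs,
                 ts_db = linear_to_db(x$sigma_bs))
}

#' @rdname preyscape_tidiers
#' @export
glance.ts_result <- function(x, ...) {
  tibble::tibble(ts_db = x$ts_db, mean_sigma_bs = x$mean_sigma_bs,
                 frequency_hz = x$config$frequency_hz,
                 g = x$config$g, h = x$config$h,
                 n_lengths = length(x$sigma_bs))
}
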