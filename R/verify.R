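#' Ground-truth density averaged into echo-integration cells
#'
#' Averages the scene's true prey density at exactly the (retained)
#' sample positions of a cleaned ping set, into the same along-track x
#' depth cells that [echo_integrate()] produces. This is the reference
#' against which the acoustic inversion is checked: with zero forward
#' noise, `sv_to_density(echo_integrate(...))` must reproduce it to
#' numerical tolerance.
#'
#' @param scene The `prey_scene` the survey was simulated over.
#' @param pings The cleaned `ping_set` (flags decide which samples count,
#'   exactly as in [echo_integrate()]).
#' @param interval_s,bin_m Cell definition, matching the integration call.
#' @return A tibble `interval`, `depth_bin`, `true_density`.
#' @export
true_density_grid <- function(scene, pings, interval_s = 30, bin_m = 1) {
  t0 <- min(pings$time)
  pings |>
    dplyr::filter(.data$flag %in% c("ok", "below_detection")) |>
    dplyr::mutate(
      interval = floor(as.numeric(difftime(.data$time, t0, units = "secs")) /
                         interval_s),
      depth_bin = bin_lower(.data$depth, bin_m),
      n_true = scene_density_at(scene, .data$x, .data$y, .data$depth)
    ) |>
    dplyr::group_by(.data$interval, .data$depth_bin) |>
    dplyr::summarise(true_density = mean(.data$n_true), .groups = "drop")
}
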