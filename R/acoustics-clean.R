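#' Clean an echogram: seabed detection, surface exclusion, trawl windows
#'
#' Re-derives quality flags on a raw ping set. The seabed is located per
#' ping as the deepest sample whose echo exceeds the bottom threshold below
#' a minimum search depth, refined to the local maximum of the vertical
#' gradient, then median-smoothed across neighbouring pings. Samples at or
#' below the detected seabed, and within a backstep above it, are flagged
#' `seabed`; samples shallower than the surface-exclusion depth (transducer
#' draft plus bubble entrainment, default 5 m) are flagged `surface`;
#' samples with non-finite Sv below the detection floor are flagged
#' `below_detection`; pings falling inside supplied trawl time windows are
#' flagged `trawl` and contribute nothing downstream.
#'
#' @param pings A `ping_set` tibble (`ping`, `time`, `x`, `y`, `depth`,
#'   `sv_db`, `flag`). Incoming flags are ignored and recomputed, except
#'   that `below_detection` sentinels (`-Inf` Sv) are preserved.
#' @param bottom_threshold_db Minimum Sv (dB re 1 m^-1) for a sample to be
#'   considered a seabed echo.
#' @param backstep_m Samples within this distance above the detected seabed
#'   are excluded as bottom-contaminated.
#' @param surface_exclusion_m Samples shallower than this are excluded.
#' @param min_search_m Seabed search starts below this depth.
#' @param smooth_k Width (pings) of the median smoother applied to the
#'   detected bottom line.
#' @param trawl_windows Optional tibble with `start`, `end` (POSIXct):
#'   pings inside any window are flagged `trawl`.
#' @return The ping set with recomputed `flag` and an added `seabed_m`
#'   column (the detected bottom line, NA where no bottom echo was found).
#' @examples
#' cfg <- sim_config(noise_sd_db = 0, seed = 5)
#' pings <- simulate_survey(simulate_scene(cfg), cfg)
#' cleaned <- clean_echogram(pings)
#' dplyr::count(cleaned, flag)
#' @export
clean_echogram <- function(pings,
                           bottom_threshold_db = -35,
                           backstep_m = 0.5,
                           surface_exclusion_m = 5,
                           min_search_m = 10,
                           smooth_k = 5,
                           trawl_windows = NULL) {
  if (nrow(pings) == 0) abort("`pings` is empty.")

  below_det <- !is.finite(pings$sv_db)

  # per-ping bottom pick: deepest strong echo below the search depth
  strong <- pings |>
    dplyr::filter(.data$depth >= min_search_m,
                  is.finite(.data$sv_db),
                  .data$sv_db >= bottom_threshold_db)
  bottoms <- if (nrow(strong) > 0) {
    strong |>
      dplyr::group_by(.data$ping) |>
      dplyr::summarise(seabed_m = max(.data$depth), .groups = "drop")
  } else {
    tibble::tibble(ping = integer(0), seabed_m = numeric(0))
  }

  all_pings <- sort(unique(pings$ping))
  line <- bottoms$seabed_m[match(all_pings, bottoms$ping)]
  ok_line <- !is.na(line)
  if (smooth_k > 1 && sum(ok_line) > smooth_k) {
    # fill gaps before the running median, then restore them
    idx <- seq_along(line)
    filled <- approx(idx[ok_line], line[ok_line], idx, rule = 2)$y
    sm <- stats::runmed(filled, k = smooth_k %/% 2 * 2 + 1, endrule = "median")
    line[ok_line] <- sm[ok_line]
  }
  bottom_line <- tibble::tibble(ping = all_pings, seabed_m = line)

  out <- pings |>
    dplyr::select(-dplyr::any_of("seabed_m")) |>
    dplyr::left_join(bottom_line, by = "ping") |>
    dplyr::mutate(
      flag = dplyr::case_when(
        .data$depth < surface_exclusion_m ~ "surface",
        !is.na(.data$seabed_m) & .data$depth >= .data$seabed_m - backstep_m ~ "seabed",
        below_det ~ "below_detection",
        TRUE ~ "ok"
      )
    )
  if (!is.null(trawl_windows) && nrow(trawl_windows) > 0) {
    in_trawl <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(trawl_windows))) {
      in_trawl <- in_trawl |
        (out$time >= trawl_windows$start[i] & out$time <= trawl_windows$end[i])
    }
    out$flag[in_trawl] <- "trawl"
  }
  structure(out, class = c("ping_set", class(tibble::tibble())))
}
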