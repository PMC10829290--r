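#' Deployment summary table for the tagged sharks
#'
#' `read_deployments()` loads the per-shark deployment summary shipped
#' with the package (identifier, sex, length, number of location
#' estimates, start and end timestamps in Australian Western Standard
#' Time) and parses the timestamps. `deployment_summary()` recomputes the
#' per-deployment tracking durations from those printed timestamps and
#' aggregates them: per-shark duration in hours, plus the maximum, total
#' and mean duration and the mean number of locations across deployments.
#'
#' @param path Path to a deployments CSV; defaults to the copy shipped in
#'   `inst/extdata`.
#' @return `read_deployments()`: a tibble with parsed `start`, `end`
#'   (POSIXct, Australia/West). `deployment_summary()`: a list with
#'   `per_shark` (tibble incl. `duration_h`) and scalars `max_duration_h`,
#'   `total_duration_h`, `mean_duration_h`, `mean_locations`.
#' @examples
#' dep <- read_deployments()
#' deployment_summary(dep)$max_duration_h
#' @export
read_deployments <- function(path = system.file("extdata", "deployments.csv",
                                                package = "preyscape")) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(
      start = as.POSIXct(.data$start_awst, tz = "Australia/West"),
      end = as.POSIXct(.data$end_awst, tz = "Australia/West")
    )
}

#' @rdname read_deployments
#' @param deployments A tibble from [read_deployments()].
#' @export
deployment_summary <- function(deployments = read_deployments()) {
  per_shark <- deployments |>
    dplyr::mutate(duration_h = as.numeric(difftime(.data$end, .data$start,
                                                   units = "hours")))
  list(
    per_shark = per_shark,
    max_duration_h = max(per_shark$duration_h),
    total_duration_h = sum(per_shark$duration_h),
    mean_duration_h = mean(per_shark$duration_h),
    mean_locations = mean(per_shark$n_locations)
  )
}
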