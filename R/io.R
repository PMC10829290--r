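#' Read and write the pipeline's delimited-text formats
#'
#' All on-disk formats are plain delimited text with ISO-8601 UTC
#' timestamps. Tag records carry `shark_id, time, depth_m, temp_c, light`;
#' fix series carry `shark_id, time, x, y, source` (source one of
#' `deployment`, `argos`, `gps`, `mote`); ping sets are long-form
#' `ping, time, x, y, depth, sv_db, flag` with `-Inf` Sv written as empty
#' (below detection); matched prey profiles are long-form
#' `shark_id, time, depth_bin, mean_density, n_cells`.
#'
#' @param path File path.
#' @return Readers return the corresponding tibble; writers return `path`
#'   invisibly.
#' @name preyscape_io
NULL

#' @rdname preyscape_io
#' @export
read_tag_record <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(time = readr::col_datetime())) |>
    check_columns(c("shark_id", "time", "depth_m", "temp_c"))
}

#' @rdname preyscape_io
#' @param record Tag record tibble.
#' @export
write_tag_record <- function(record, path) {
  readr::write_csv(record, path)
  invisible(path)
}

#' @rdname preyscape_io
#' @export
read_fixes <- function(path) {
  fx <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(time = readr::col_datetime())) |>
    check_columns(c("shark_id", "time", "x", "y", "source"))
  bad <- setdiff(unique(fx$source), c("deployment", "argos", "gps", "mote"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown fix source(s): %s.", paste(bad, collapse = ", ")))
  }
  fx
}

#' @rdname preyscape_io
#' @param fixes Fix tibble.
#' @export
write_fixes <- function(fixes, path) {
  readr::write_csv(fixes, path)
  invisible(path)
}

#' @rdname preyscape_io
#' @export
read_pings <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(time = readr::col_datetime())) |>
    check_columns(c("ping", "time", "x", "y", "depth", "sv_db"))
  if (!"flag" %in% names(p)) p$flag <- "ok"
  p$flag[!is.finite(p$sv_db) & p$flag == "ok"] <- "below_detection"
  p$sv_db[is.na(p$sv_db)] <- -Inf
  structure(p, class = c("ping_set", class(tibble::tibble())))
}

#' @rdname preyscape_io
#' @param pings Ping set tibble.
#' @export
write_pings <- function(pings, path) {
  out <- pings
  out$sv_db[!is.finite(out$sv_db)] <- NA_real_
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname preyscape_io
#' @param profile A `matched_profile` from [match_buffer()].
#' @export
write_matched_profile <- function(profile, path) {
  readr::write_csv(
    profile[c("shark_id", "time", "depth_bin", "mean_density", "n_cells")],
    path
  )
  invisible(path)
}

#' Export UD isopleth polygons as GeoJSON
#'
#' Writes each isopleth level of a 2D utilisation distribution as a
#' GeoJSON MultiPolygon feature in the local metric coordinate frame.
#'
#' @param ud A `ud_surface` from [ud_2d()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isopleths_geojson <- function(ud, path) {
  features <- purrr::imap(ud$polygons, function(rings, name) {
    coords <- lapply(rings, function(r) {
      xy <- cbind(r$x, r$y)
      if (!all(xy[1, ] == xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
      list(lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1], xy[i, 2])))
    })
    list(
      type = "Feature",
      properties = list(level = name),
      geometry = list(type = "MultiPolygon", coordinates = coords)
    )
  })
  gj <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

check_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  df
}
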