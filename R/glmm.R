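#' Regress horizontal space use on acoustic prey biomass
#'
#' Linear model of per-cell utilisation-distribution value against NASC
#' expressed in dB, `10 log10(NASC + eps)`, on the shared 500-m analysis
#' grid: the horizontal test of whether the predator concentrates where
#' acoustic prey biomass is high. Returns the slope with its 95% CI and
#' r^2 in the common `habitat_fit` container.
#'
#' @param cells Tibble with one row per grid cell: `ud` (UD value) and
#'   `nasc` (m^2 nmi^-2); >= 10 complete cells.
#' @param eps Offset inside the log, so zero-NASC cells stay defined.
#' @param log_ud Model `log(ud)` rather than `ud` as the response.
#' @return An object of class `habitat_fit` (see [fit_tad_density()]).
#' @examples
#' cells <- tibble::tibble(nasc = exp(rnorm(50, 4, 1)))
#' cells$ud <- 0.1 + 0.02 * 10 * log10(cells$nasc + 1) + rnorm(50, 0, 0.01)
#' fit_ud_nasc(cells)
#' @export
fit_ud_nasc <- function(cells, eps = 1, log_ud = FALSE) {
  cells <- cells[complete.cases(cells[c("ud", "nasc")]), ]
  if (nrow(cells) < 10) abort("Need >= 10 grid cells with both UD and NASC.")
  cells$nasc_db <- 10 * log10(cells$nasc + eps)
  if (var(cells$nasc_db) == 0) abort("Degenerate design: NASC has zero variance.")
  cells$response <- if (log_ud) log(cells$ud) else cells$ud
  fit <- lm(response ~ nasc_db, data = cells)
  ci <- confint(fit)["nasc_db", ]
  new_habitat_fit(
    label = sprintf("%s ~ nasc_db", if (log_ud) "log(UD)" else "UD"),
    fit = fit,
    coefs = tibble::tibble(
      term = names(coef(fit)),
      estimate = unname(coef(fit)),
      std_error = unname(summary(fit)$coefficients[, "Std. Error"]),
      conf_low = unname(confint(fit)[, 1]),
      conf_high = unname(confint(fit)[, 2])
    ),
    r2 = summary(fit)$r.squared,
    ranef_var = NA_real_, resid_var = summary(fit)$sigma^2,
    ranef_share = NA_real_,
    aic = AIC(fit), n_obs = nrow(cells), n_groups = NA_integer_
  )
}

#' Mixed model of time-at-depth against matched prey density
#'
#' Fits `TAD ~ density + (1 | shark)` by maximum likelihood with
#' \pkg{lme4}: shark time-at-depth per 1-m depth bin as the response,
#' buffer-matched mean prey density as the predictor, and a per-shark
#' random intercept against pseudo-replication. The depth range can be
#' restricted (e.g. `c(5, 50)` for the shallow subset). By default the
#' response is `log(TAD + 1)` since TAD is a nonnegative duration with a
#' long tail; set `log_response = FALSE` for the raw scale. Reports the
#' fixed slope with Wald 95% CI, marginal (fixed-effects) r^2, the
#' random-intercept variance and its share of the total, and the
#' ML AIC (valid for comparison against the null `TAD ~ 1 + (1 | shark)`
#' via [compare_waic()]).
#'
#' With a single shark the model falls back to a fixed-effects `lm` with a
#' warning.
#'
#' @param data Tibble with `shark_id`, `depth_bin`, `tad_s` (seconds) and
#'   `density` (ind m^-3); >= 20 rows.
#' @param depth_range `"all"` or numeric `c(min, max)` in m.
#' @param log_response Model `log(tad_s + 1)`.
#' @return An object of class `habitat_fit`: list with `label`, `coefs`
#'   (tibble term/estimate/std_error/conf_low/conf_high), `r2`
#'   (marginal), `ranef_var`, `resid_var`, `ranef_share`, `aic`, `n_obs`,
#'   `n_groups` and the underlying `fit`.
#' @examples
#' set.seed(3)
#' d <- tidyr::expand_grid(shark_id = paste0("WS", 1:4), depth_bin = 5:30)
#' d$density <- runif(nrow(d), 0, 10)
#' d$tad_s <- exp(2 + 0.1 * d$density + rnorm(nrow(d), 0, 0.3))
#' fit_tad_density(d)
#' @export
fit_tad_density <- function(data, depth_range = "all", log_response = TRUE) {
  need <- c("shark_id", "depth_bin", "tad_s", "density")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (is.numeric(depth_range)) {
    data <- dplyr::filter(data, .data$depth_bin >= depth_range[1],
                          .data$depth_bin < depth_range[2])
  }
  data <- data[complete.cases(data[need]), ]
  if (nrow(data) < 20) abort("Need >= 20 (shark, depth-bin) rows.")
  if (var(data$density) == 0) abort("Degenerate design: density has zero variance.")
  data$response <- if (log_response) log(data$tad_s + 1) else data$tad_s

  n_sharks <- length(unique(data$shark_id))
  if (n_sharks < 2) {
    warn("Single shark: falling back to a fixed-effects fit.")
    fit <- lm(response ~ density, data = data)
    s <- summary(fit)
    return(new_habitat_fit(
      label = "TAD ~ density (fixed effects)",
      fit = fit,
      coefs = tibble::tibble(
        term = names(coef(fit)), estimate = unname(coef(fit)),
        std_error = unname(s$coefficients[, "Std. Error"]),
        conf_low = unname(confint(fit)[, 1]),
        conf_high = unname(confint(fit)[, 2])
      ),
      r2 = s$r.squared, ranef_var = NA_real_, resid_var = s$sigma^2,
      ranef_share = NA_real_, aic = AIC(fit), n_obs = nrow(data),
      n_groups = 1L
    ))
  }

  fit <- lme4::lmer(response ~ density + (1 | shark_id), data = data,
                    REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_b <- vc$vcov[vc$grp == "shark_id"]
  var_e <- vc$vcov[vc$grp == "Residual"]
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  var_fixed <- var(as.vector(stats::model.matrix(fit) %*% fe))
  new_habitat_fit(
    label = "TAD ~ density + (1 | shark)",
    fit = fit,
    coefs = tibble::tibble(
      term = names(fe), estimate = unname(fe), std_error = unname(se),
      conf_low = unname(fe - qnorm(0.975) * se),
      conf_high = unname(fe + qnorm(0.975) * se)
    ),
    r2 = var_fixed / (var_fixed + var_b + var_e),
    ranef_var = var_b, resid_var = var_e,
    ranef_share = var_b / (var_b + var_e),
    aic = AIC(fit), n_obs = nrow(data), n_groups = n_sharks
  )
}

#' Null companion of [fit_tad_density()]
#'
#' Fits `TAD ~ 1 + (1 | shark)` on the same rows by maximum likelihood,
#' for the Akaike-weight comparison.
#'
#' @inheritParams fit_tad_density
#' @return A `habitat_fit`.
#' @export
fit_tad_null <- function(data, depth_range = "all", log_response = TRUE) {
  if (is.numeric(depth_range)) {
    data <- dplyr::filter(data, .data$depth_bin >= depth_range[1],
                          .data$depth_bin < depth_range[2])
  }
  data <- data[complete.cases(data[c("shark_id", "tad_s")]), ]
  data$response <- if (log_response) log(data$tad_s + 1) else data$tad_s
  fit <- lme4::lmer(response ~ 1 + (1 | shark_id), data = data, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_b <- vc$vcov[vc$grp == "shark_id"]
  var_e <- vc$vcov[vc$grp == "Residual"]
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  new_habitat_fit(
    label = "TAD ~ 1 + (1 | shark)", fit = fit,
    coefs = tibble::tibble(term = names(fe), estimate = unname(fe),
                           std_error = unname(se),
                           conf_low = unname(fe - qnorm(0.975) * se),
                           conf_high = unname(fe + qnorm(0.975) * se)),
    r2 = 0, ranef_var = var_b, resid_var = var_e,
    ranef_share = var_b / (var_b + var_e),
    aic = AIC(fit), n_obs = nrow(data),
    n_groups = length(unique(data$shark_id))
  )
}

new_habitat_fit <- function(label, fit, coefs, r2, ranef_var, resid_var,
                            ranef_share, aic, n_obs, n_groups) {
  structure(
    list(label = label, fit = fit, coefs = coefs, r2 = r2,
         ranef_var = ranef_var, resid_var = resid_var,
         ranef_share = ranef_share, aic = aic, n_obs = n_obs,
         n_groups = n_groups),
    class = "habitat_fit"
  )
}

#' @export
print.habitat_fit <- function(x, ...) {
  cat("<habitat_fit>", x$label, "\n")
  print(x$coefs)
  cat(sprintf("  marginal r^2 = %.3f; AIC = %.1f; n = %d", x$r2, x$aic, x$n_obs))
  if (!is.na(x$ranef_share)) {
    cat(sprintf("; random effect (%d groups) share of variance = %.2f",
                x$n_groups, x$ranef_share))
  }
  cat("\n")
  invisible(x)
}

#' Akaike-weight comparison of candidate models
#'
#' Computes `w_m = exp(-Delta_m / 2) / sum_k exp(-Delta_k / 2)` with
#' `Delta = AIC - min(AIC)`: the relative evidence for each model within
#' the compared set. All fits must be on the same observations.
#'
#' @param ... `habitat_fit` objects (or a single list of them), fitted to
#'   identical data.
#' @return A tibble of class `model_comparison`: `model`, `aic`,
#'   `delta_aic`, `weight`, `preferred`.
#' @examples
#' set.seed(4)
#' d <- tidyr::expand_grid(shark_id = paste0("WS", 1:4), depth_bin = 5:30)
#' d$density <- runif(nrow(d), 0, 10)
#' d$tad_s <- exp(2 + 0.2 * d$density + rnorm(nrow(d), 0, 0.3))
#' compare_waic(fit_tad_density(d), fit_tad_null(d))
#' @export
compare_waic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "habitat_fit")) {
    fits <- fits[[1]]
  }
  if (length(fits) < 2) abort("Need >= 2 fits to compare.")
  n_obs <- vapply(fits, function(f) f$n_obs, integer(1))
  if (length(unique(n_obs)) > 1) {
    abort("Fits are on differing numbers of observations; AIC weights are not comparable.")
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- tibble::tibble(
    model = vapply(fits, function(f) f$label, character(1)),
    aic = aic, delta_aic = delta, weight = w,
    preferred = seq_along(w) == which.max(w)
  )
  structure(out, class = c("model_comparison", class(tibble::tibble())))
}
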