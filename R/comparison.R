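#' Nested chi-square test on deviances
#'
#' The difference in deviance between two nested hierarchy levels follows a
#' chi-square distribution with degrees of freedom equal to the difference
#' in the number of free parameters; a significantly large statistic means
#' the finer-grained model is a real improvement.
#'
#' @param dev_simple,dev_complex deviances of the coarser and finer model.
#' @param k_simple,k_complex their free-parameter counts
#'   (`k_complex > k_simple`).
#' @return A one-row tibble: `dev_simple, dev_complex, k_simple, k_complex,
#'   chi2_stat, df, p_value`. A negative statistic (complex model fits
#'   worse) warns and reports `p_value = 1`.
#' @export
#' @examples
#' chi2_deviance_test(-1423, -1804, 5, 15)
chi2_deviance_test <- function(dev_simple, dev_complex, k_simple, k_complex) {
  if (k_complex <= k_simple) {
    stop("k_complex must exceed k_simple for a nested comparison", call. = FALSE)
  }
  stat <- dev_simple - dev_complex
  df <- k_complex - k_simple
  if (stat < 0) {
    warning("complex model fits worse than the simple one (negative statistic)",
            call. = FALSE)
    p <- 1
  } else {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  }
  tibble::tibble(dev_simple = dev_simple, dev_complex = dev_complex,
                 k_simple = k_simple, k_complex = k_complex,
                 chi2_stat = stat, df = df, p_value = p)
}

#' Deviance information criterion
#'
#' Spiegelhalter's DIC from a posterior deviance trace:
#' `pD = mean(D) - D(posterior means)`, `DIC = mean(D) + pD`.
#'
#' @param deviance_trace per-draw deviances.
#' @param deviance_at_mean deviance evaluated at the posterior-mean
#'   parameters.
#' @return A one-row tibble: `mean_deviance, deviance_at_mean, p_d, dic`.
#' @export
dic <- function(deviance_trace, deviance_at_mean) {
  if (length(deviance_trace) == 0) stop("empty deviance trace", call. = FALSE)
  dbar <- mean(deviance_trace)
  p_d <- dbar - deviance_at_mean
  tibble::tibble(mean_deviance = dbar, deviance_at_mean = deviance_at_mean,
                 p_d = p_d, dic = dbar + p_d)
}

#' Pearson correlation between predicted and measured conductance
#'
#' @param predicted,measured equal-length numeric vectors (n >= 3).
#' @return Pearson product-moment correlation.
#' @export
pred_obs_correlation <- function(predicted, measured) {
  if (length(predicted) != length(measured) || length(predicted) < 3) {
    stop("need two equal-length vectors of at least 3 values", call. = FALSE)
  }
  if (stats::sd(predicted) == 0 || stats::sd(measured) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(predicted, measured)
}

#' Compare mean fitted soil water potentials between two groups
#'
#' Welch two-sample t-test (two-sided) on the fitted daily soil water
#' potentials of two functional groups, as used to ask whether subshrubs
#' experienced wetter soils than the legume shrubs.
#'
#' @param psi_a,psi_b MPa values for the two groups (each n >= 2).
#' @return A one-row tibble: `mean_a, mean_b, t_stat, df, p_value`.
#' @export
group_psi_ttest <- function(psi_a, psi_b) {
  if (length(psi_a) < 2 || length(psi_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(psi_a) == 0 && stats::sd(psi_b) == 0) {
    if (isTRUE(all.equal(mean(psi_a), mean(psi_b)))) {
      return(tibble::tibble(mean_a = mean(psi_a), mean_b = mean(psi_b),
                            t_stat = 0, df = NA_real_, p_value = 1))
    }
    stop("degenerate variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(psi_a, psi_b, var.equal = FALSE)
  tibble::tibble(mean_a = mean(psi_a), mean_b = mean(psi_b),
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Deviance comparison table across the three hierarchy levels
#'
#' Assembles the level-by-level summary (deviance, DIC, parameter counts,
#' residual SD, predicted-measured correlation) and the two nested
#' chi-square tests (PFT vs GLB, OBS vs PFT) from a fitted hierarchy.
#'
#' @param fits named list of `stomatal_fit` objects (`OBS`, `PFT`, `GLB`)
#'   as returned by [fit_hierarchy()].
#' @param data the record tibble the fits were run on (for the
#'   predicted-measured correlations).
#' @return list with `levels` (tibble, one row per level) and `tests`
#'   (tibble, one row per nested comparison).
#' @export
compare_levels <- function(fits, data) {
  stopifnot(all(c("OBS", "PFT", "GLB") %in% names(fits)))
  lev <- purrr::map_dfr(fits[c("GLB", "PFT", "OBS")], function(f) {
    pred <- predict_gs(data, f$params, f$psi_day,
                       by = f$unit_col %||% "obs_id")$gs_pred
    cbind(glance(f), tibble::tibble(correlation = pred_obs_correlation(pred, data$gs_mol)))
  })
  dbar <- vapply(fits, function(f) mean(f$deviance_trace), numeric(1))
  tests <- dplyr::bind_rows(
    dplyr::mutate(
      chi2_deviance_test(dbar[["GLB"]], dbar[["PFT"]],
                         fits$GLB$n_free_parameters, fits$PFT$n_free_parameters),
      comparison = "PFT vs GLB", .before = 1),
    dplyr::mutate(
      chi2_deviance_test(dbar[["PFT"]], dbar[["OBS"]],
                         fits$PFT$n_free_parameters, fits$OBS$n_free_parameters),
      comparison = "OBS vs PFT", .before = 1)
  )
  list(levels = lev, tests = tests)
}
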