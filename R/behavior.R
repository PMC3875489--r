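# Favorable-corner conventions of the response-surface analysis:
# near-field-capacity soil and near-saturated air.
PSI_FAVORABLE <- -0.033   # MPa
D_FAVORABLE <- 0.0035     # dimensionless
A_N_REFERENCE <- 6.5      # umol m-2 s-1, approx. group-mean assimilation

#' Stomatal-conductance response surface over (psi, D)
#'
#' Evaluates the coupled model on a lattice of soil water potential by
#' scaled vapor pressure deficit at fixed assimilation, the quantitative
#' content of a contour-plot response surface.
#'
#' @param params one-row parameter tibble.
#' @param psi_axis soil water potentials, MPa (all <= -0.001).
#' @param d_axis scaled VPD values.
#' @param a_n fixed net photosynthesis, umol m-2 s-1.
#' @param c_i intercellular CO2 (default: reference `c_0`).
#' @return A tibble of class `"behavior_grid"` in long form:
#'   `psi_soil, d, g_s`, with the parameter label and `a_n` as attributes.
#' @export
#' @examples
#' response_surface(pft_params("SUBS"), seq(-2.5, -0.033, length.out = 5),
#'                  c(0.0035, 0.02, 0.05))
response_surface <- function(params, psi_axis, d_axis, a_n = A_N_REFERENCE,
                             c_i = NULL) {
  stopifnot(nrow(params) == 1, length(psi_axis) > 0, length(d_axis) > 0)
  if (any(psi_axis > -0.001)) stop("psi_axis values must be <= -0.001 MPa", call. = FALSE)
  grid <- tidyr::expand_grid(psi_soil = psi_axis, d = d_axis)
  sol <- solve_leaf(params, psi_soil = grid$psi_soil, d = grid$d, a_n = a_n,
                    c_i = c_i)
  out <- tibble::tibble(psi_soil = grid$psi_soil, d = grid$d, g_s = sol$g_s)
  structure(out, class = c("behavior_grid", class(out)),
            params_label = params$label[1], a_n = a_n)
}

#' Soil water potential of stomatal closure
#'
#' The soil water potential at which modeled conductance first reaches zero.
#' Closure happens when the soil can no longer be opposed by the adjusted
#' osmotic pressure, so the closure potential is `-pi(a_n)` independent of
#' the evaporative demand; a bisection on the forward model at small demand
#' confirms the analytic value (`method = "bisect"`).
#'
#' @param params one-row parameter tibble.
#' @param a_n net photosynthesis at which to evaluate, umol m-2 s-1.
#' @param c_i intercellular CO2 (default: reference `c_0`).
#' @param method `"analytic"` (default) or `"bisect"`.
#' @param d demand used by the bisection probe.
#' @return closure soil water potential, MPa.
#' @export
#' @examples
#' closure_potential(pft_params("SUBS"))
closure_potential <- function(params, a_n = A_N_REFERENCE, c_i = NULL,
                              method = c("analytic", "bisect"), d = 0.001) {
  method <- match.arg(method)
  stopifnot(nrow(params) == 1)
  pi_adj <- osmotic_pressure(params, a_n, c_i)
  if (method == "analytic") return(-pi_adj)
  lo <- -pi_adj - 1; hi <- -0.001
  g_at <- function(p) solve_leaf(params, p, d, a_n, c_i)$g_s
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    if (g_at(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Ensemble mean and SD curves across parameter sets
#'
#' Sweeps the forward model along soil water potential (at fixed demand) or
#' along demand (at fixed soil water potential) for every parameter set in
#' a table, and returns the pointwise arithmetic mean and standard
#' deviation of conductance - the ensemble summary used to compare
#' observation-level behavior between functional groups.
#'
#' @param param_sets parameter tibble, one row per set (>= 2 rows).
#' @param x values of the swept variable.
#' @param sweep `"psi"` (sweep soil water potential, `fixed` = D) or
#'   `"d"` (sweep demand, `fixed` = soil water potential in MPa).
#' @param fixed value of the variable held constant (default: D = 0.03 for
#'   a psi-sweep, psi = -1 MPa for a D-sweep).
#' @param a_n fixed net photosynthesis.
#' @param by optional grouping column of `param_sets` (e.g. `"pft"`):
#'   curves are then computed per group.
#' @return tibble `x, mean, sd, n` (plus the grouping column if `by` given).
#' @export
ensemble_curves <- function(param_sets, x, sweep = c("psi", "d"), fixed = NULL,
                            a_n = A_N_REFERENCE, by = NULL) {
  sweep <- match.arg(sweep)
  if (nrow(param_sets) < 2) stop("need at least 2 parameter sets", call. = FALSE)
  fixed <- fixed %||% if (sweep == "psi") 0.03 else -1.0
  one_curve <- function(p) {
    if (sweep == "psi") solve_leaf(p, psi_soil = x, d = fixed, a_n = a_n)$g_s
    else solve_leaf(p, psi_soil = fixed, d = x, a_n = a_n)$g_s
  }
  summarise_sets <- function(sets) {
    gs <- vapply(seq_len(nrow(sets)), function(i) one_curve(sets[i, ]),
                 numeric(length(x)))
    if (is.null(dim(gs))) gs <- matrix(gs, nrow = length(x))
    tibble::tibble(x = x, mean = rowMeans(gs),
                   sd = apply(gs, 1, stats::sd), n = nrow(sets))
  }
  if (is.null(by)) return(summarise_sets(param_sets))
  purrr::map_dfr(split(param_sets, param_sets[[by]]), summarise_sets,
                 .id = by)
}

#' Mean xylem vulnerability curve and half-loss point
#'
#' Averages the cavitation-limited soil-to-leaf conductance `K(psi_x)`
#' across parameter sets on a tension axis, and locates the tension at which
#' the mean curve falls to half its value at zero tension (a P50-like
#' summary), by bisection.
#'
#' @param param_sets parameter tibble (>= 1 row).
#' @param psi_x_axis xylem water potentials, MPa (<= 0), descending or not.
#' @return list with `curve` (tibble `psi_x, k_mean, k_sd`) and `half_loss`
#'   (MPa; the root of `mean K(psi_x) = mean K(0) / 2`).
#' @export
#' @examples
#' vulnerability_curve(pft_params(c("DCDS", "SUBS")), seq(-30, 0, by = 0.5))
vulnerability_curve <- function(param_sets, psi_x_axis) {
  stopifnot(nrow(param_sets) >= 1)
  k_mat <- vapply(seq_len(nrow(param_sets)),
                  function(i) hydraulic_conductance(param_sets[i, ], psi_x_axis),
                  numeric(length(psi_x_axis)))
  if (is.null(dim(k_mat))) k_mat <- matrix(k_mat, nrow = length(psi_x_axis))
  curve <- tibble::tibble(psi_x = psi_x_axis, k_mean = rowMeans(k_mat),
                          k_sd = apply(k_mat, 1, stats::sd))
  mean_k <- function(p) {
    mean(hydraulic_conductance_(param_sets$g_p, param_sets$c_lambda, p))
  }
  half <- mean_k(0) / 2
  lo <- 0
  hi <- -1
  while (mean_k(hi) > half) hi <- hi * 2
  for (i in seq_len(80)) {
    mid <- (lo + hi) / 2
    if (mean_k(mid) > half) lo <- mid else hi <- mid
  }
  list(curve = curve, half_loss = (lo + hi) / 2)
}

#' Forward behavioral benchmarks for a set of parameter tables
#'
#' Computes the standard benchmark numbers of the behavioral analysis for
#' each parameter set: conductance at the favorable-moisture corner
#' (psi = -0.033 MPa, D = 0.0035), conductance under wet soil but high
#' demand (D = 0.05), and the closure soil water potential, all at the
#' reference assimilation of 6.5 umol m-2 s-1.
#'
#' @param params parameter tibble (one row per set).
#' @param a_n reference net photosynthesis.
#' @return tibble: `label, gs_favorable, gs_high_demand, psi_closure`.
#' @export
#' @examples
#' behavior_benchmarks(pft_params())
behavior_benchmarks <- function(params, a_n = A_N_REFERENCE) {
  purrr::map_dfr(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    tibble::tibble(
      label = p$label,
      gs_favorable = solve_leaf(p, PSI_FAVORABLE, D_FAVORABLE, a_n)$g_s,
      gs_high_demand = solve_leaf(p, PSI_FAVORABLE, 0.05, a_n)$g_s,
      psi_closure = closure_potential(p, a_n)
    )
  })
}
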