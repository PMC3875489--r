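#' Construct a table of stomatal model parameters
#'
#' One row per parameter set (a species-site observation, a functional group,
#' or a pooled global fit). All conductances are molar: `g_p` is in
#' mol H2O m-2 s-1 MPa-1 internally (published tables usually print mmol;
#' see [pft_params()] and [obs_params()], which convert on construction).
#'
#' @param label character, name of the unit the parameters belong to.
#' @param k_psi guard-cell apparent compliance, mol H2O m-2 s-1 MPa-1.
#' @param g_p maximum soil-to-leaf hydraulic conductance, mol H2O m-2 s-1 MPa-1.
#' @param c_lambda cavitation tradeoff constant, m2 s mol-1: the fractional
#'   loss rate of hydraulic conductance per MPa of xylem tension scales with
#'   `c_lambda * g_p`, so more efficient xylem is more vulnerable.
#' @param pi_0 baseline osmotic pressure, MPa.
#' @param k_i osmotic-adjustment half-saturation, umol CO2 m-2 s-1.
#' @param xi osmotic-adjustment gain, dimensionless.
#' @param c_0 reference CO2 mole fraction, umol mol-1.
#'
#' @return A tibble with one row per parameter set and columns
#'   `label, k_psi, g_p, c_lambda, pi_0, k_i, xi, c_0`.
#' @export
#' @examples
#' stomatal_params("demo", k_psi = 0.5, g_p = 0.004, c_lambda = 3.13,
#'                 pi_0 = 1.8, k_i = 300, xi = 20)
stomatal_params <- function(label, k_psi, g_p, c_lambda, pi_0, k_i, xi,
                            c_0 = 370) {
  out <- tibble::tibble(
    label = as.character(label),
    k_psi = as.numeric(k_psi), g_p = as.numeric(g_p),
    c_lambda = as.numeric(c_lambda), pi_0 = as.numeric(pi_0),
    k_i = as.numeric(k_i), xi = as.numeric(xi), c_0 = as.numeric(c_0)
  )
  validate_params(out)
  out
}

validate_params <- function(p) {
  stopifnot(is.data.frame(p))
  need <- c("k_psi", "g_p", "c_lambda", "pi_0", "k_i", "xi", "c_0")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("parameter table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  with(p, {
    if (any(k_psi < 0.01 | k_psi > 1.5)) stop("k_psi outside [0.01, 1.5]", call. = FALSE)
    if (any(g_p <= 0)) stop("g_p must be > 0", call. = FALSE)
    if (any(c_lambda <= 0)) stop("c_lambda must be > 0", call. = FALSE)
    if (any(pi_0 <= 0 | pi_0 > 3)) stop("pi_0 outside (0, 3]", call. = FALSE)
    if (any(k_i <= 0)) stop("k_i must be > 0", call. = FALSE)
    if (any(xi < 0)) stop("xi must be >= 0", call. = FALSE)
  })
  invisible(p)
}

#' Published functional-group and global parameter estimates
#'
#' Posterior-mean parameter values for the three shrub functional groups
#' (DCDS: deciduous non-legume shrubs; LEGM: deciduous legume shrubs;
#' SUBS: *Artemisia* subshrubs) and the pooled global fit (GLB), as estimated
#' from the synthesis of north-China diurnal gas-exchange observations.
#' `g_p` is converted from the published mmol m-2 s-1 MPa-1 to mol;
#' the shared cavitation tradeoff constant is `c_lambda` = 3.13 m2 s mol-1.
#'
#' @param groups which parameter sets to return; any subset of
#'   `c("GLB", "DCDS", "LEGM", "SUBS")`.
#' @param c_0 reference CO2 mole fraction, umol mol-1.
#' @return A parameter tibble as from [stomatal_params()].
#' @export
#' @examples
#' pft_params("SUBS")
pft_params <- function(groups = c("GLB", "DCDS", "LEGM", "SUBS"), c_0 = 370) {
  groups <- match.arg(groups, several.ok = TRUE)
  tab <- tibble::tibble(
    label    = c("GLB", "DCDS", "LEGM", "SUBS"),
    k_psi    = c(0.38, 0.16, 0.70, 1.42),
    g_p_mmol = c(3.60, 2.57, 2.05, 5.66),
    k_i      = c(202.6, 198.8, 284.0, 319.8),
    pi_0     = c(1.76, 1.91, 1.94, 1.87),
    xi       = c(25.5, 23.8, 34.1, 9.9)
  )
  tab <- tab[match(groups, tab$label), ]
  stomatal_params(tab$label, tab$k_psi, tab$g_p_mmol / 1000, 3.13,
                  tab$pi_0, tab$k_i, tab$xi, c_0 = c_0)
}

#' Published observation-level parameter estimates
#'
#' Posterior-mean parameter values for the 43 individual species-by-site
#' observations, with their functional group. `g_p` is converted from the
#' published mmol to mol m-2 s-1 MPa-1; `c_lambda` is the shared 3.13.
#'
#' @param c_0 reference CO2 mole fraction, umol mol-1.
#' @return A parameter tibble (43 rows) with an extra `pft` column.
#' @export
obs_params <- function(c_0 = 370) {
  pft <- c("DCDS","DCDS","DCDS","LEGM","DCDS","LEGM","LEGM","LEGM","SUBS","SUBS",
           "SUBS","LEGM","SUBS","DCDS","SUBS","LEGM","LEGM","DCDS","LEGM","DCDS",
           "SUBS","DCDS","LEGM","SUBS","DCDS","DCDS","DCDS","DCDS","SUBS","LEGM",
           "DCDS","LEGM","LEGM","LEGM","SUBS","LEGM","LEGM","SUBS","LEGM","LEGM",
           "LEGM","DCDS","DCDS")
  k_psi <- c(0.088,0.552,0.380,0.454,0.297,0.591,0.639,0.734,0.228,0.508,
             1.084,0.927,1.461,1.034,0.986,0.576,1.034,0.460,1.307,0.526,
             0.282,0.263,1.407,1.482,0.322,0.345,0.311,0.180,0.311,0.262,
             1.090,0.845,0.246,0.565,0.599,0.551,0.452,0.807,0.236,0.636,
             0.157,0.745,0.407)
  g_p_mmol <- c(33.11,28.10,20.08,18.14,26.79,10.95,17.16,10.57,25.90,22.16,
                11.64,1.94,5.06,2.77,1.47,9.83,1.66,19.17,3.90,6.42,
                30.17,20.60,2.82,8.28,20.99,19.93,22.57,27.62,22.94,25.18,
                0.87,1.71,23.21,26.70,8.05,38.58,50.90,55.83,18.59,5.95,
                23.07,2.56,12.50)
  k_i <- c(295.4,326.8,324.1,330.1,329.7,330.1,333.9,329.9,345.8,338.7,
           345.1,362.5,369.7,302.1,227.2,41.4,67.7,308.3,219.8,45.3,
           316.3,304.4,26.5,331.1,305.4,311.0,308.1,313.2,314.0,305.6,
           27.4,319.5,271.1,325.6,303.0,320.1,341.6,314.9,298.9,323.0,
           317.9,325.9,309.5)
  pi_0 <- c(0.95,1.30,1.02,1.02,1.02,1.54,1.04,1.20,1.41,1.09,
            1.51,1.39,1.95,1.39,1.16,0.94,1.26,1.12,1.74,1.04,
            1.54,1.06,1.35,1.98,0.71,0.76,0.77,0.85,0.82,0.78,
            1.43,1.55,1.21,1.31,1.17,1.38,1.69,1.86,1.15,1.43,
            1.27,1.50,1.32)
  xi <- c(149.6,9.8,99.0,79.8,69.1,2.9,12.0,11.9,26.0,27.4,
          2.9,88.7,15.7,45.8,135.1,5.6,38.3,36.5,34.2,49.3,
          8.8,191.7,3.6,1.7,149.0,151.9,148.7,140.8,152.0,162.8,
          10.6,113.5,130.4,33.9,158.1,30.9,51.5,7.4,205.1,87.9,
          150.3,119.3,150.7)
  out <- stomatal_params(sprintf("obs%02d", seq_along(k_psi)),
                         k_psi, g_p_mmol / 1000, 3.13, pi_0, k_i, xi, c_0 = c_0)
  dplyr::mutate(out, pft = pft, .after = "label")
}
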