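#' Guard-cell osmotic pressure with photosynthesis-driven adjustment
#'
#' Osmotic pressure rises above its baseline as net photosynthesis supplies
#' osmotica, saturating with half-saturation `k_i` and gain `xi`, and scaled
#' by the CO2 ratio `c_0 / c_i`:
#' `pi = pi_0 * (1 + xi * An / (k_i + An) * c_0 / c_i)`.
#' Negative assimilation (pre-dawn respiration) contributes no adjustment:
#' the Michaelis term is floored at zero.
#'
#' @param params a parameter tibble (one row, or recycled against the data),
#'   see [stomatal_params()].
#' @param a_n net photosynthesis, umol CO2 m-2 s-1.
#' @param c_i intercellular CO2 mole fraction, umol mol-1; `NA` or `NULL`
#'   defaults to the reference `c_0` (neutral CO2 factor).
#' @return osmotic pressure, MPa (>= `pi_0` whenever `a_n >= 0`).
#' @export
#' @examples
#' osmotic_pressure(pft_params("SUBS"), a_n = 6.5)
osmotic_pressure <- function(params, a_n, c_i = NULL) {
  osmotic_pressure_(params$pi_0, params$xi, params$k_i, a_n, c_i, params$c_0)
}

osmotic_pressure_ <- function(pi_0, xi, k_i, a_n, c_i, c_0) {
  if (is.null(c_i)) c_i <- c_0
  c_i <- ifelse(is.na(c_i), c_0, c_i)
  if (any(c_i <= 0)) stop("c_i must be positive", call. = FALSE)
  if (any(k_i + a_n <= 0)) {
    stop("k_i + a_n must be positive (osmotic term undefined)", call. = FALSE)
  }
  frac <- pmax(a_n, 0) / (k_i + pmax(a_n, 0))
  pi_0 * (1 + xi * frac * (c_0 / c_i))
}

#' Soil-to-leaf hydraulic conductance under cavitation
#'
#' Hyperbolic decline of whole-plant hydraulic conductance with xylem
#' tension: `K(psi_x) = g_p / (1 + c_lambda * g_p * |psi_x|)`. Because the
#' loss rate scales with `c_lambda * g_p`, more efficient xylem (larger
#' `g_p`, i.e. wider vessels) loses a given fraction of its conductance at a
#' smaller tension - the efficiency-safety tradeoff. The half-loss tension is
#' `-1 / (c_lambda * g_p)`.
#'
#' @param params a parameter tibble, see [stomatal_params()].
#' @param psi_x xylem water potential, MPa (must be <= 0).
#' @return conductance, mol H2O m-2 s-1 MPa-1, in `(0, g_p]`.
#' @export
#' @examples
#' hydraulic_conductance(pft_params("SUBS"), psi_x = c(0, -5, -15))
hydraulic_conductance <- function(params, psi_x) {
  if (any(psi_x > 0)) stop("psi_x must be <= 0 (xylem under tension)", call. = FALSE)
  hydraulic_conductance_(params$g_p, params$c_lambda, psi_x)
}

hydraulic_conductance_ <- function(g_p, c_lambda, psi_x) {
  g_p / (1 + c_lambda * g_p * abs(psi_x))
}

# Mass balance residual f(psi_x) = supply - demand at candidate psi_x:
# demand  g_s * D = k_psi * max(0, pi + psi_x) * D
# supply  K(psi_x) * (psi_soil - psi_x)
mass_balance_ <- function(psi_x, k_psi, g_p, c_lambda, pi, psi_soil, d) {
  k_psi * pmax(pi + psi_x, 0) * d -
    hydraulic_conductance_(g_p, c_lambda, psi_x) * (psi_soil - psi_x)
}

# closed-form root of the mass balance: quadratic in psi_x,
#   a*c*x^2 - (a*(1 - c*pi) + g_p)*x - (a*pi - g_p*psi) = 0,
# a = k_psi*d, c = c_lambda*g_p. Vectorized; assumes open stomata
# (psi_soil > -pi) and d > 0. Numerically stable two-root formula; the
# physical root lies in [-pi, psi_soil].
solve_psix_closed_ <- function(k_psi, g_p, c_lambda, pi, psi_soil, d,
                               warn_two_roots = TRUE) {
  a <- k_psi * d
  cc <- c_lambda * g_p
  qa <- a * cc
  qb <- -(a * (1 - cc * pi) + g_p)
  qc <- -(a * pi - g_p * psi_soil)

  n <- max(length(qa), length(qb), length(qc), length(pi), length(psi_soil))
  qa <- rep_len(qa, n); qb <- rep_len(qb, n); qc <- rep_len(qc, n)
  pi <- rep_len(pi, n); psi_soil <- rep_len(psi_soil, n)

  out <- numeric(n)
  lin <- qa < 1e-14 * pmax(abs(qb), 1e-300)  # c_lambda -> 0: linear balance
  out[lin] <- -qc[lin] / qb[lin]
  if (any(!lin)) {
    i <- which(!lin)
    disc <- pmax(qb[i]^2 - 4 * qa[i] * qc[i], 0)
    q <- -0.5 * (qb[i] + sign(qb[i]) * sqrt(disc))
    r1 <- q / qa[i]
    r2 <- ifelse(q != 0, qc[i] / q, r1)
    tol <- 1e-9
    in1 <- r1 >= -pi[i] - tol & r1 <= psi_soil[i] + tol
    in2 <- r2 >= -pi[i] - tol & r2 <= psi_soil[i] + tol
    both <- in1 & in2 & abs(r1 - r2) > tol
    if (any(both) && warn_two_roots) {
      warning("both quadratic roots fall in [-pi, psi_soil]; ",
              "taking the larger-turgor root", call. = FALSE)
    }
    pick <- ifelse(both, pmax(r1, r2), ifelse(in1, r1, r2))
    # guard against roundoff just outside the bracket
    out[i] <- pmin(pmax(pick, -pi[i]), psi_soil[i])
  }
  out
}

# bracketing bisection on the mass balance over [-pi, psi_soil]; vectorized.
solve_psix_bisect_ <- function(k_psi, g_p, c_lambda, pi, psi_soil, d,
                               tol = 1e-12) {
  n <- max(length(k_psi), length(g_p), length(pi), length(psi_soil), length(d))
  lo <- rep_len(-pi, n)            # f(lo) <= 0: zero demand, positive supply
  hi <- rep_len(psi_soil, n)       # f(hi) >= 0: positive demand, zero supply
  k_psi <- rep_len(k_psi, n); g_p <- rep_len(g_p, n)
  c_lambda <- rep_len(c_lambda, n); d <- rep_len(d, n)
  pi <- rep_len(pi, n); psi_soil <- rep_len(psi_soil, n)
  for (iter in seq_len(80)) {
    mid <- 0.5 * (lo + hi)
    f <- mass_balance_(mid, k_psi, g_p, c_lambda, pi, psi_soil, d)
    up <- f <= 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
    if (max(hi - lo) < tol) break
  }
  0.5 * (lo + hi)
}

#' Solve the coupled leaf water balance for stomatal conductance
#'
#' Finds the steady state where (a) stomatal conductance is proportional to
#' guard-cell turgor, `g_s = k_psi * max(0, pi + psi_x)`, and (b) the
#' transpiration stream balances soil-to-leaf supply,
#' `g_s * D = K(psi_x) * (psi_soil - psi_x)`, with `K` the cavitation-limited
#' conductance of [hydraulic_conductance()] and `pi` the adjusted osmotic
#' pressure of [osmotic_pressure()]. The balance is a quadratic in `psi_x`
#' solved in closed form; a bracketing bisection on `[-pi, psi_soil]` is
#' available as an independent check (`method = "bisect"`). When the soil is
#' drier than the osmotic pressure can oppose (`psi_soil <= -pi`) the stomata
#' are closed: `g_s = 0`, `psi_x = psi_soil`.
#'
#' All environmental arguments are vectorized; `params` must be a single row
#' or have as many rows as the longest argument.
#'
#' @param params a parameter tibble, see [stomatal_params()].
#' @param psi_soil soil water potential, MPa (<= 0).
#' @param d scaled vapor pressure deficit, dimensionless (>= 0).
#' @param a_n net photosynthesis, umol CO2 m-2 s-1.
#' @param c_i intercellular CO2, umol mol-1 (default: the reference `c_0`).
#' @param method `"closed"` (quadratic formula, default) or `"bisect"`
#'   (bracketing bisection to `tol`).
#' @param tol bisection tolerance on `psi_x`, MPa.
#' @return A tibble with one row per evaluated condition:
#'   `psi_soil, d, a_n, psi_x, pi, turgor, K, g_s, E`.
#' @export
#' @examples
#' solve_leaf(pft_params("SUBS"), psi_soil = -0.033, d = 0.0035, a_n = 6.5)
solve_leaf <- function(params, psi_soil, d, a_n, c_i = NULL,
                       method = c("closed", "bisect"), tol = 1e-12) {
  method <- match.arg(method)
  if (any(psi_soil > 0)) stop("psi_soil must be <= 0", call. = FALSE)
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  n <- max(length(psi_soil), length(d), length(a_n), nrow(params),
           length(c_i %||% 1))
  if (!nrow(params) %in% c(1L, n)) {
    stop("params must have 1 row or one row per condition", call. = FALSE)
  }
  idx <- if (nrow(params) == 1L) rep(1L, n) else seq_len(n)
  k_psi <- params$k_psi[idx]; g_p <- params$g_p[idx]
  c_lambda <- params$c_lambda[idx]
  psi_soil <- rep_len(psi_soil, n); d <- rep_len(d, n); a_n <- rep_len(a_n, n)
  if (!is.null(c_i)) c_i <- rep_len(c_i, n)

  pi <- osmotic_pressure_(params$pi_0[idx], params$xi[idx], params$k_i[idx],
                          a_n, c_i, params$c_0[idx])

  psi_x <- psi_soil  # closed-stomata / zero-demand default
  open <- psi_soil > -pi & d > 0
  if (any(open)) {
    i <- which(open)
    psi_x[i] <- if (method == "closed") {
      solve_psix_closed_(k_psi[i], g_p[i], c_lambda[i], pi[i], psi_soil[i], d[i])
    } else {
      solve_psix_bisect_(k_psi[i], g_p[i], c_lambda[i], pi[i], psi_soil[i], d[i],
                         tol = tol)
    }
  }
  g_s <- pmax(0, k_psi * (pi + psi_x))
  tibble::tibble(
    psi_soil = psi_soil, d = d, a_n = a_n,
    psi_x = psi_x, pi = pi, turgor = pmax(pi + psi_x, 0),
    K = hydraulic_conductance_(g_p, c_lambda, psi_x),
    g_s = g_s, E = g_s * d
  )
}

#' Transpiration from conductance and demand
#'
#' @param g_s stomatal conductance, mol H2O m-2 s-1.
#' @param d scaled vapor pressure deficit, dimensionless.
#' @return transpiration `E = g_s * d`, mol H2O m-2 s-1.
#' @export
transpiration <- function(g_s, d) g_s * d

#' Predict stomatal conductance for a record table
#'
#' Batch-evaluates [solve_leaf()] over a harmonized gas-exchange table,
#' matching each record's unit (observation, functional group, or the pooled
#' dataset) to a row of the parameter table, and using a per-day soil water
#' potential.
#'
#' @param data record tibble with columns `an_umol`, `ci_umol`, `vpd_kpa`,
#'   `p_kpa`, a unit column, and `date`.
#' @param params parameter tibble whose `label` column matches `data[[by]]`
#'   (or a single row applied to all records).
#' @param psi per-day soil water potentials: a tibble with columns
#'   `obs_id`, `date`, `psi`, or a single number applied everywhere.
#' @param by name of the unit column in `data` matched against
#'   `params$label`; default `"obs_id"`.
#' @return `data` with a `gs_pred` column appended.
#' @export
predict_gs <- function(data, params, psi, by = "obs_id") {
  if (is.numeric(psi) && length(psi) == 1) {
    psi_vec <- rep(psi, nrow(data))
  } else {
    key <- paste(data$obs_id, data$date)
    lut <- stats::setNames(psi$psi, paste(psi$obs_id, psi$date))
    psi_vec <- unname(lut[key])
    if (any(is.na(psi_vec))) {
      stop("missing soil water potential for some observation-days", call. = FALSE)
    }
  }
  prow <- if (nrow(params) == 1L) {
    params[rep(1L, nrow(data)), ]
  } else {
    m <- match(data[[by]], params$label)
    if (any(is.na(m))) stop("some records have no matching parameter row", call. = FALSE)
    params[m, ]
  }
  sol <- solve_leaf(prow, psi_soil = psi_vec,
                    d = data$vpd_kpa / data$p_kpa,
                    a_n = data$an_umol, c_i = data$ci_umol)
  dplyr::mutate(data, gs_pred = sol$g_s)
}
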