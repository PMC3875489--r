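#' Uniform prior bounds for the hierarchical fit
#'
#' Physiologically meaningful bounded-uniform priors for every free quantity.
#' Bounds envelope the published observation- and group-level estimates with
#' margin; the compliance bounds `k_psi` in [0.01, 1.5] are the published
#' prior; the latent daily soil water potential may reach -8 MPa, reflecting
#' the high drought tolerance of shrubs.
#'
#' @param ... overrides as `name = c(lower, upper)`; names among
#'   `k_psi, g_p, k_i, pi_0, xi, c_lambda, psi_day, sigma`.
#' @return named list of length-2 numeric vectors.
#' @export
prior_spec <- function(...) {
  p <- list(
    k_psi = c(0.01, 1.5),       # mol m-2 s-1 MPa-1
    g_p = c(0.0005, 0.08),      # mol m-2 s-1 MPa-1
    k_i = c(20, 400),           # umol m-2 s-1
    pi_0 = c(0.5, 2.0),         # MPa
    xi = c(0, 250),
    c_lambda = c(0.1, 10),      # m2 s mol-1
    psi_day = c(-8, -0.01),     # MPa
    sigma = c(0.001, 1)         # mol m-2 s-1
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(p)) stop("unknown prior: ", nm, call. = FALSE)
    p[[nm]] <- over[[nm]]
  }
  for (nm in names(p)) {
    if (p[[nm]][1] >= p[[nm]][2]) stop("prior lower >= upper for ", nm, call. = FALSE)
  }
  p
}

#' MCMC settings
#'
#' @param iterations iterations per chain (first half is burn-in and is
#'   discarded; proposal scales adapt only during burn-in).
#' @param chains number of independent chains (>= 2 for convergence checks).
#' @param seed integer; chain `i` uses `seed + i`.
#' @param adapt adapt proposal scales during burn-in toward an acceptance
#'   rate in `target_accept`.
#' @param target_accept length-2 acceptance-rate window for adaptation.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param init `"warm"` (default): chains start from a deterministic
#'   alternating least-squares solution (unit parameters by bounded
#'   `nlminb`, each day's latent potential by 1-D optimization), jittered
#'   per chain - the usual remedy for slow burn-in of strongly correlated
#'   nonlinear hierarchies. `"prior"`: chains start from independent prior
#'   draws.
#' @return a list of settings.
#' @export
mcmc_control <- function(iterations = 5000, chains = 2, seed = 1L,
                         adapt = TRUE, target_accept = c(0.2, 0.5), thin = 1L,
                         init = c("warm", "prior")) {
  list(iterations = as.integer(iterations), chains = as.integer(chains),
       seed = as.integer(seed), adapt = adapt,
       target_accept = target_accept, thin = as.integer(thin),
       init = match.arg(init))
}

#' Gaussian log-likelihood of a record table under the model
#'
#' Sum over records of the Normal log-density of measured conductance around
#' the model prediction, with a single residual SD.
#'
#' @param data record tibble (needs `gs_mol` plus the [predict_gs()] inputs).
#' @param params parameter tibble matched to records via `by`.
#' @param psi per-day soil water potential table (`obs_id, date, psi`) or a
#'   single number.
#' @param sigma residual SD, mol m-2 s-1.
#' @param by unit column of `data` matched against `params$label`.
#' @return log-likelihood (scalar).
#' @export
log_likelihood <- function(data, params, psi, sigma, by = "obs_id") {
  pred <- predict_gs(data, params, psi, by = by)$gs_pred
  sum(stats::dnorm(data$gs_mol, pred, sigma, log = TRUE))
}

#' Deviance
#'
#' `D = -2 * logLik`. For conductance data mostly below 1 mol m-2 s-1 the
#' Normal densities exceed 1 and the deviance is negative.
#'
#' @param log_lik log-likelihood value(s).
#' @return deviance value(s).
#' @export
deviance_from_loglik <- function(log_lik) -2 * log_lik

# fast forward prediction, no tibbles; all arguments vectors of equal length
# (or scalars). Used in the sampler's hot path.
gs_forward_ <- function(k_psi, g_p, c_lambda, pi_0, k_i, xi, c_0,
                        psi, d, an, ci) {
  n <- length(psi)
  k_psi <- rep_len(k_psi, n); g_p <- rep_len(g_p, n)
  c_lambda <- rep_len(c_lambda, n)
  an0 <- pmax(an, 0)
  pi <- rep_len(pi_0 * (1 + xi * an0 / (k_i + an0) * (c_0 / ci)), n)
  psi_x <- psi
  open <- psi > -pi & d > 0
  if (any(open)) {
    i <- which(open)
    psi_x[i] <- solve_psix_closed_(k_psi[i], g_p[i], c_lambda[i],
                                   pi[i], psi[i], d[i],
                                   warn_two_roots = FALSE)
  }
  pmax(0, k_psi * (pi + psi_x))
}

# reflect a proposal into [lo, hi]; O(1) modular folding so arbitrarily
# large proposal scales stay safe
reflect_ <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  lo + y
}

UNIT_PARS <- c("k_psi", "g_p", "k_i", "pi_0", "xi")

#' Fit the stomatal model at one hierarchical level
#'
#' Metropolis-within-Gibbs sampling of the model parameters under
#' bounded-uniform priors and an i.i.d. Gaussian likelihood on measured
#' stomatal conductance with a single residual SD per level. Three nesting
#' levels are supported:
#'
#' * `"OBS"`: one parameter set per observation (species x site), plus one
#'   latent soil water potential per observation-day and a single cavitation
#'   tradeoff constant `c_lambda` shared by all observations.
#' * `"PFT"`: one parameter set per functional group; the daily soil water
#'   potentials and `c_lambda` must be supplied (normally the posterior
#'   means of a prior OBS fit).
#' * `"GLB"`: a single pooled parameter set; `psi_fixed` and `c_lambda`
#'   as for PFT.
#'
#' Each scalar parameter is updated in turn by a Gaussian random-walk
#' proposal reflected at its prior bounds (reflection is symmetric, so the
#' uniform-prior Metropolis ratio is just the likelihood ratio). Proposal
#' scales adapt during burn-in toward the control's target acceptance
#' window and are then frozen; the first half of every chain is discarded.
#'
#' @param data harmonized record tibble (see [read_gas_exchange()] /
#'   [generate_dataset()]); must have `obs_id, pft, date, hour, leaf,
#'   gs_mol, an_umol, ci_umol, vpd_kpa, p_kpa`.
#' @param level `"OBS"`, `"PFT"` or `"GLB"`.
#' @param priors a [prior_spec()].
#' @param control an [mcmc_control()].
#' @param psi_fixed for PFT/GLB: tibble `obs_id, date, psi` of daily soil
#'   water potentials (e.g. `fit$psi_day` from an OBS fit).
#' @param c_lambda for PFT/GLB: the fixed tradeoff constant (e.g. the OBS
#'   posterior mean).
#' @param c_0 reference CO2 mole fraction.
#' @return An object of class `"stomatal_fit"`; see [tidy.stomatal_fit()]
#'   and [glance.stomatal_fit()].
#' @export
fit_level <- function(data, level = c("OBS", "PFT", "GLB"),
                      priors = prior_spec(), control = mcmc_control(),
                      psi_fixed = NULL, c_lambda = NULL, c_0 = 370) {
  level <- match.arg(level)
  if (level != "OBS") {
    if (is.null(psi_fixed) || is.null(c_lambda)) {
      stop(level, "-level fits need `psi_fixed` and `c_lambda` from a prior ",
           "OBS-level fit", call. = FALSE)
    }
  }
  n <- nrow(data)
  if (n == 0) stop("empty record table", call. = FALSE)

  unit_col <- switch(level, OBS = "obs_id", PFT = "pft", GLB = NULL)
  unit_lab <- if (is.null(unit_col)) rep("GLB", n) else data[[unit_col]]
  units <- sort(unique(unit_lab))
  unit_of <- match(unit_lab, units)
  rows_by_unit <- split(seq_len(n), unit_of)

  od_tab <- dplyr::distinct(data[, c("obs_id", "date")])
  od_tab <- dplyr::arrange(od_tab, .data$obs_id, .data$date)
  od_key <- paste(od_tab$obs_id, od_tab$date)
  od_of <- match(paste(data$obs_id, data$date), od_key)
  rows_by_od <- split(seq_len(n), od_of)
  n_od <- nrow(od_tab)

  psi_is_free <- level == "OBS"
  if (!psi_is_free) {
    lut <- stats::setNames(psi_fixed$psi, paste(psi_fixed$obs_id, psi_fixed$date))
    psi_od_fixed <- unname(lut[od_key])
    if (any(is.na(psi_od_fixed))) {
      stop("psi_fixed does not cover every observation-day", call. = FALSE)
    }
  }

  y <- data$gs_mol
  d_rec <- data$vpd_kpa / data$p_kpa
  an_rec <- data$an_umol
  ci_rec <- ifelse(is.na(data$ci_umol), c_0, data$ci_umol)

  n_units <- length(units)
  n_free <- n_units * 5L + if (psi_is_free) n_od + 1L else 0L

  par_names <- c(
    as.vector(t(outer(units, UNIT_PARS, paste, sep = "."))),
    if (psi_is_free) c(paste0("psi.", od_key), "c_lambda"),
    "sigma")

  keep_iters <- seq.int(floor(control$iterations / 2) + 1L, control$iterations,
                        by = control$thin)

  chains <- vector("list", control$chains)
  dev_chains <- vector("list", control$chains)
  acc_chains <- vector("list", control$chains)

  warm <- NULL
  if (identical(control$init, "warm")) {
    set.seed(control$seed)
    warm <- warm_init_(y = y, d_rec = d_rec, an_rec = an_rec, ci_rec = ci_rec,
                       c_0 = c_0, unit_of = unit_of,
                       rows_by_unit = rows_by_unit, od_of = od_of,
                       rows_by_od = rows_by_od, psi_is_free = psi_is_free,
                       psi_od_fixed = if (psi_is_free) NULL else psi_od_fixed,
                       c_lambda_fixed = if (psi_is_free) NULL else c_lambda,
                       priors = priors, n_units = n_units)
  }

  for (ch in seq_len(control$chains)) {
    set.seed(control$seed + ch)
    res <- run_mwg_chain_(
      init_state = warm,
      y = y, d_rec = d_rec, an_rec = an_rec, ci_rec = ci_rec, c_0 = c_0,
      unit_of = unit_of, rows_by_unit = rows_by_unit,
      od_of = od_of, rows_by_od = rows_by_od,
      psi_is_free = psi_is_free,
      psi_od_fixed = if (psi_is_free) NULL else psi_od_fixed,
      c_lambda_fixed = if (psi_is_free) NULL else c_lambda,
      priors = priors, control = control, keep_iters = keep_iters,
      n_units = n_units)
    chains[[ch]] <- res$draws
    dev_chains[[ch]] <- res$deviance
    acc_chains[[ch]] <- res$acc_rate
  }

  draws <- do.call(rbind, chains)
  colnames(draws) <- par_names
  chain_id <- rep(seq_len(control$chains), each = length(keep_iters))

  post_mean <- colMeans(draws)
  rhat <- split_rhat_(chains)
  names(rhat) <- par_names

  params_hat <- tibble::tibble(
    label = units,
    k_psi = post_mean[paste0(units, ".k_psi")],
    g_p = post_mean[paste0(units, ".g_p")],
    c_lambda = if (psi_is_free) post_mean[["c_lambda"]] else c_lambda,
    pi_0 = post_mean[paste0(units, ".pi_0")],
    k_i = post_mean[paste0(units, ".k_i")],
    xi = post_mean[paste0(units, ".xi")],
    c_0 = c_0)

  psi_day <- tibble::tibble(
    obs_id = od_tab$obs_id, date = od_tab$date,
    psi = if (psi_is_free) unname(post_mean[paste0("psi.", od_key)]) else psi_od_fixed)

  # plug-in deviance at the posterior means (for DIC)
  ll_hat <- log_likelihood(data, params_hat, psi_day,
                           sigma = post_mean[["sigma"]],
                           by = if (is.null(unit_col)) "obs_id" else unit_col)

  structure(list(
    level = level, draws = draws, chain = chain_id, par_names = par_names,
    params = params_hat, psi_day = psi_day,
    c_lambda = if (psi_is_free) post_mean[["c_lambda"]] else c_lambda,
    residual_sd = post_mean[["sigma"]],
    deviance_trace = unlist(dev_chains, use.names = FALSE),
    deviance_at_mean = deviance_from_loglik(ll_hat),
    n_free_parameters = n_free,
    n_records = n, units = units, unit_col = unit_col,
    rhat = rhat, acceptance = Reduce(`+`, acc_chains) / length(acc_chains),
    priors = priors, control = control
  ), class = "stomatal_fit")
}

# one chain of the Metropolis-within-Gibbs sampler; state is kept in plain
# vectors, predictions cached per record, SSE maintained incrementally.
run_mwg_chain_ <- function(y, d_rec, an_rec, ci_rec, c_0,
                           unit_of, rows_by_unit, od_of, rows_by_od,
                           psi_is_free, psi_od_fixed, c_lambda_fixed,
                           priors, control, keep_iters, n_units,
                           init_state = NULL) {
  n <- length(y)
  n_od <- length(rows_by_od)
  b <- priors

  # initial state: jittered warm start, or independent prior draws
  # (likelihood is finite everywhere, but keep the re-draw guard for
  # degenerate inputs)
  draw_unit <- function() {
    vapply(UNIT_PARS, function(p) stats::runif(1, b[[p]][1], b[[p]][2]),
           numeric(1))
  }
  up <- matrix(0, n_units, 5, dimnames = list(NULL, UNIT_PARS))
  psi_od <- NULL; cl <- NULL
  for (try in seq_len(100)) {
    if (!is.null(init_state)) {
      jit <- function(x, lo, hi, rel = 0.03) {
        vapply(x, function(xi) {
          reflect_(xi + stats::rnorm(1, 0, rel * (hi - lo)), lo, hi)
        }, numeric(1))
      }
      for (pj in seq_len(5)) {
        p <- UNIT_PARS[pj]
        up[, pj] <- jit(init_state$up[, pj], b[[p]][1], b[[p]][2])
      }
      psi_od <- if (psi_is_free) {
        jit(init_state$psi_od, b$psi_day[1], b$psi_day[2])
      } else psi_od_fixed
      cl <- if (psi_is_free) {
        jit(init_state$cl, b$c_lambda[1], b$c_lambda[2])
      } else c_lambda_fixed
      sigma <- jit(init_state$sigma, b$sigma[1], b$sigma[2])
    } else {
      for (u in seq_len(n_units)) up[u, ] <- draw_unit()
      psi_od <- if (psi_is_free) {
        stats::runif(n_od, b$psi_day[1], b$psi_day[2])
      } else psi_od_fixed
      cl <- if (psi_is_free) stats::runif(1, b$c_lambda[1], b$c_lambda[2]) else c_lambda_fixed
      sigma <- stats::runif(1, max(b$sigma[1], 0.01), b$sigma[2])
    }
    pred <- predict_rows_(seq_len(n), up, psi_od, cl, c_0,
                          unit_of, od_of, d_rec, an_rec, ci_rec)
    sse <- sum((y - pred)^2)
    if (is.finite(sse)) break
    if (try == 100) stop("could not initialize the sampler", call. = FALSE)
    init_state <- NULL  # fall back to prior draws if the warm start fails
  }

  # proposal scales and acceptance bookkeeping
  sc_up <- matrix(0, n_units, 5, dimnames = list(NULL, UNIT_PARS))
  for (p in UNIT_PARS) sc_up[, p] <- 0.1 * diff(b[[p]])
  sc_psi <- rep(0.1 * diff(b$psi_day), n_od)
  sc_cl <- 0.1 * diff(b$c_lambda)
  sc_sig <- 0.1 * diff(b$sigma)
  n_par_blocks <- n_units * 5 + if (psi_is_free) n_od + 1 else 0
  acc <- numeric(n_par_blocks + 1)
  acc_win <- numeric(n_par_blocks + 1)
  win <- 0L
  burn <- floor(control$iterations / 2)

  loglik_const <- -0.5 * n * log(2 * pi)
  ll_of <- function(sse, sigma) loglik_const - n * log(sigma) - sse / (2 * sigma^2)

  n_keep <- length(keep_iters)
  p_total <- n_units * 5 + (if (psi_is_free) n_od + 1 else 0) + 1
  draws <- matrix(NA_real_, n_keep, p_total)
  devs <- numeric(n_keep)
  k_out <- 1L

  for (it in seq_len(control$iterations)) {
    blk <- 0L
    # --- per-unit structural parameters ---
    for (u in seq_len(n_units)) {
      rows <- rows_by_unit[[u]]
      y_u <- y[rows]
      sse_u <- sum((y_u - pred[rows])^2)
      for (pj in seq_len(5)) {
        blk <- blk + 1L
        p <- UNIT_PARS[pj]
        old <- up[u, pj]
        cand <- reflect_(old + stats::rnorm(1, 0, sc_up[u, pj]),
                         b[[p]][1], b[[p]][2])
        up[u, pj] <- cand
        new_pred_u <- predict_rows_(rows, up, psi_od, cl, c_0,
                                    unit_of, od_of, d_rec, an_rec, ci_rec)
        sse_u_new <- sum((y_u - new_pred_u)^2)
        if (log(stats::runif(1)) < (sse_u - sse_u_new) / (2 * sigma^2)) {
          sse <- sse + sse_u_new - sse_u
          sse_u <- sse_u_new
          pred[rows] <- new_pred_u
          acc[blk] <- acc[blk] + 1; acc_win[blk] <- acc_win[blk] + 1
        } else {
          up[u, pj] <- old
        }
      }
    }
    # --- latent daily soil water potentials and shared c_lambda (OBS) ---
    if (psi_is_free) {
      for (k in seq_len(n_od)) {
        blk <- blk + 1L
        rows <- rows_by_od[[k]]
        y_k <- y[rows]
        sse_k <- sum((y_k - pred[rows])^2)
        old <- psi_od[k]
        psi_od[k] <- reflect_(old + stats::rnorm(1, 0, sc_psi[k]),
                              b$psi_day[1], b$psi_day[2])
        new_pred_k <- predict_rows_(rows, up, psi_od, cl, c_0,
                                    unit_of, od_of, d_rec, an_rec, ci_rec)
        sse_k_new <- sum((y_k - new_pred_k)^2)
        if (log(stats::runif(1)) < (sse_k - sse_k_new) / (2 * sigma^2)) {
          sse <- sse + sse_k_new - sse_k
          pred[rows] <- new_pred_k
          acc[blk] <- acc[blk] + 1; acc_win[blk] <- acc_win[blk] + 1
        } else {
          psi_od[k] <- old
        }
      }
      blk <- blk + 1L
      old <- cl
      cl <- reflect_(old + stats::rnorm(1, 0, sc_cl), b$c_lambda[1], b$c_lambda[2])
      new_pred <- predict_rows_(seq_len(n), up, psi_od, cl, c_0,
                                unit_of, od_of, d_rec, an_rec, ci_rec)
      sse_new <- sum((y - new_pred)^2)
      if (log(stats::runif(1)) < (sse - sse_new) / (2 * sigma^2)) {
        sse <- sse_new
        pred <- new_pred
        acc[blk] <- acc[blk] + 1; acc_win[blk] <- acc_win[blk] + 1
      } else {
        cl <- old
      }
    }
    # --- residual SD ---
    blk <- blk + 1L
    old <- sigma
    cand <- reflect_(old + stats::rnorm(1, 0, sc_sig), b$sigma[1], b$sigma[2])
    if (log(stats::runif(1)) < ll_of(sse, cand) - ll_of(sse, old)) {
      sigma <- cand
      acc[blk] <- acc[blk] + 1; acc_win[blk] <- acc_win[blk] + 1
    }

    # --- adaptation during burn-in ---
    win <- win + 1L
    if (control$adapt && it <= burn && win == 25L) {
      rate <- acc_win / 25
      fac <- ifelse(rate > control$target_accept[2], 1.25,
                    ifelse(rate < control$target_accept[1], 0.8, 1))
      f_up <- matrix(fac[seq_len(n_units * 5)], n_units, 5, byrow = TRUE)
      sc_up <- sc_up * f_up
      for (p in UNIT_PARS) {
        sc_up[, p] <- pmin(sc_up[, p], 5 * diff(b[[p]]))  # scale cap
      }
      if (psi_is_free) {
        sc_psi <- pmin(sc_psi * fac[n_units * 5 + seq_len(n_od)],
                       5 * diff(b$psi_day))
        sc_cl <- min(sc_cl * fac[n_units * 5 + n_od + 1], 5 * diff(b$c_lambda))
      }
      sc_sig <- min(sc_sig * fac[length(fac)], 5 * diff(b$sigma))
      acc_win[] <- 0
      win <- 0L
    }
    if (win == 25L) win <- 0L

    if (k_out <= n_keep && it == keep_iters[k_out]) {
      draws[k_out, ] <- c(as.vector(t(up)),
                          if (psi_is_free) c(psi_od, cl),
                          sigma)
      devs[k_out] <- -2 * ll_of(sse, sigma)
      k_out <- k_out + 1L
    }
  }
  list(draws = draws, deviance = devs,
       acc_rate = acc / control$iterations)
}

# Deterministic warm start for the sampler: alternate bounded least squares
# for each unit's structural parameters (nlminb) with 1-D optimization of
# each observation-day's latent soil water potential, then set sigma from
# the residuals. With the latent potentials free the surface is strongly
# ridged, and chains started from prior draws need very long burn-in;
# starting them near this alternating-least-squares solution (with per-chain
# jitter) makes the prescribed chain lengths productive.
warm_init_ <- function(y, d_rec, an_rec, ci_rec, c_0, unit_of, rows_by_unit,
                       od_of, rows_by_od, psi_is_free, psi_od_fixed,
                       c_lambda_fixed, priors, n_units, rounds = 3) {
  b <- priors
  n_od <- length(rows_by_od)
  lo <- vapply(UNIT_PARS, function(p) b[[p]][1], numeric(1))
  hi <- vapply(UNIT_PARS, function(p) b[[p]][2], numeric(1))
  up <- matrix((lo + hi) / 2, n_units, 5, byrow = TRUE,
               dimnames = list(NULL, UNIT_PARS))
  psi_od <- if (psi_is_free) rep(-1, n_od) else psi_od_fixed
  cl <- if (psi_is_free) mean(b$c_lambda) else c_lambda_fixed
  # unit of each obs-day (an observation's records share one unit)
  od_unit <- vapply(rows_by_od, function(r) unit_of[r[1]], integer(1))

  if (!psi_is_free) rounds <- 1
  for (r in seq_len(rounds)) {
    for (u in seq_len(n_units)) {
      rows <- rows_by_unit[[u]]
      obj <- function(th) {
        gs <- gs_forward_(th[1], th[2], cl, th[4], th[3], th[5], c_0,
                          psi_od[od_of[rows]], d_rec[rows], an_rec[rows],
                          ci_rec[rows])
        sum((y[rows] - gs)^2)
      }
      opt <- stats::nlminb(up[u, ], obj, lower = lo, upper = hi,
                           control = list(iter.max = 200))
      up[u, ] <- opt$par
    }
    if (psi_is_free) {
      for (k in seq_len(n_od)) {
        rows <- rows_by_od[[k]]
        u <- od_unit[k]
        obj_psi <- function(p) {
          gs <- gs_forward_(up[u, 1], up[u, 2], cl, up[u, 4], up[u, 3],
                            up[u, 5], c_0, rep(p, length(rows)), d_rec[rows],
                            an_rec[rows], ci_rec[rows])
          sum((y[rows] - gs)^2)
        }
        psi_od[k] <- stats::optimize(obj_psi, b$psi_day)$minimum
      }
    }
  }
  n <- length(y)
  pred <- predict_rows_(seq_len(n), up, psi_od, cl, c_0,
                        unit_of, od_of, d_rec, an_rec, ci_rec)
  sigma <- min(max(sqrt(sum((y - pred)^2) / n), b$sigma[1]), b$sigma[2])
  list(up = up, psi_od = psi_od, cl = cl, sigma = sigma)
}

# cached forward prediction for a subset of records
predict_rows_ <- function(rows, up, psi_od, cl, c_0,
                          unit_of, od_of, d_rec, an_rec, ci_rec) {
  u <- unit_of[rows]
  gs_forward_(k_psi = up[u, 1], g_p = up[u, 2], c_lambda = cl,
              pi_0 = up[u, 4], k_i = up[u, 3], xi = up[u, 5], c_0 = c_0,
              psi = psi_od[od_of[rows]], d = d_rec[rows],
              an = an_rec[rows], ci = ci_rec[rows])
}

# split-half Gelman-Rubin R-hat over a list of per-chain draw matrices
split_rhat_ <- function(chains) {
  halves <- list()
  for (m in chains) {
    h <- floor(nrow(m) / 2)
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[seq.int(h + 1, 2 * h), , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1]])))
  vars <- vapply(halves, function(m) apply(m, 2, stats::var),
                 numeric(ncol(halves[[1]])))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1)
  }
  B <- n * apply(means, 1, stats::var)
  W <- rowMeans(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Two-pass hierarchical fitting workflow
#'
#' Runs the observation-level fit first (free daily soil water potentials
#' and shared `c_lambda`), then feeds its posterior-mean potentials and
#' `c_lambda` into the functional-group and global fits - the staged
#' procedure of the original analysis.
#'
#' @param data harmonized record tibble.
#' @param priors a [prior_spec()].
#' @param control_obs,control_grp [mcmc_control()] for the OBS pass and the
#'   PFT/GLB passes.
#' @param c_0 reference CO2 mole fraction.
#' @return named list of `stomatal_fit` objects: `OBS`, `PFT`, `GLB`.
#' @export
fit_hierarchy <- function(data, priors = prior_spec(),
                          control_obs = mcmc_control(),
                          control_grp = control_obs, c_0 = 370) {
  obs <- fit_level(data, "OBS", priors, control_obs, c_0 = c_0)
  pft <- fit_level(data, "PFT", priors, control_grp,
                   psi_fixed = obs$psi_day, c_lambda = obs$c_lambda, c_0 = c_0)
  glb <- fit_level(data, "GLB", priors, control_grp,
                   psi_fixed = obs$psi_day, c_lambda = obs$c_lambda, c_0 = c_0)
  list(OBS = obs, PFT = pft, GLB = glb)
}

#' Bounded maximum-likelihood deviance at one level
#'
#' Minimizes the residual sum of squares over the per-unit structural
#' parameters (with the daily soil water potentials and `c_lambda` fixed),
#' profiles out the Gaussian residual SD analytically, and returns the
#' likelihood-ratio deviance. With `psi` and `c_lambda` fixed the units are
#' independent, so each unit's five parameters are optimized separately
#' (`nlminb` within the prior bounds). This is the deviance the nested
#' chi-square comparison's sampling theory refers to, and is cheap enough
#' for repeated-simulation calibration.
#'
#' @param data harmonized record tibble.
#' @param level `"OBS"`, `"PFT"` or `"GLB"`.
#' @param psi_fixed tibble `obs_id, date, psi`.
#' @param c_lambda fixed tradeoff constant.
#' @param priors a [prior_spec()] providing the box constraints.
#' @param c_0 reference CO2 mole fraction.
#' @param n_starts random multistarts per unit (the mid-bounds point is
#'   always tried first).
#' @param start_params optional extra start points: a parameter tibble (a
#'   single row applied to every unit, or rows matched to units by `label`),
#'   or a list of such tibbles. Starting the finer model from the coarser
#'   model's optimum nests the optimizations, which guarantees a
#'   non-negative deviance difference.
#' @return list with `deviance`, `k` (free-parameter count, 5 per unit),
#'   `sigma` (profiled residual SD) and `params` (the optimum).
#' @export
fit_deviance_ml <- function(data, level = c("OBS", "PFT", "GLB"),
                            psi_fixed, c_lambda, priors = prior_spec(),
                            c_0 = 370, n_starts = 3, start_params = NULL) {
  level <- match.arg(level)
  unit_col <- switch(level, OBS = "obs_id", PFT = "pft", GLB = NULL)
  unit_lab <- if (is.null(unit_col)) rep("GLB", nrow(data)) else data[[unit_col]]
  units <- sort(unique(unit_lab))

  lut <- stats::setNames(psi_fixed$psi, paste(psi_fixed$obs_id, psi_fixed$date))
  psi_rec <- unname(lut[paste(data$obs_id, data$date)])
  if (any(is.na(psi_rec))) stop("psi_fixed does not cover all days", call. = FALSE)
  d_rec <- data$vpd_kpa / data$p_kpa
  ci_rec <- ifelse(is.na(data$ci_umol), c_0, data$ci_umol)

  lo <- vapply(UNIT_PARS, function(p) priors[[p]][1], numeric(1))
  hi <- vapply(UNIT_PARS, function(p) priors[[p]][2], numeric(1))

  sse_total <- 0
  par_rows <- vector("list", length(units))
  for (ui in seq_along(units)) {
    rows <- which(unit_lab == units[ui])
    obj <- function(th) {
      gs <- gs_forward_(th[1], th[2], c_lambda, th[4], th[3], th[5], c_0,
                        psi_rec[rows], d_rec[rows], data$an_umol[rows],
                        ci_rec[rows])
      sum((data$gs_mol[rows] - gs)^2)
    }
    starts <- list((lo + hi) / 2)
    sp_list <- if (is.null(start_params)) list()
               else if (is.data.frame(start_params)) list(start_params)
               else start_params
    for (sp in sp_list) {
      row <- if (nrow(sp) == 1L) 1L else match(units[ui], sp$label)
      if (!is.na(row)) {
        starts <- c(starts, list(unlist(sp[row, UNIT_PARS])))
      }
    }
    for (s in seq_len(max(n_starts - 1, 0))) {
      starts <- c(starts, list(stats::runif(5, lo, hi)))
    }
    best <- NULL
    for (start in starts) {
      start <- pmin(pmax(start, lo), hi)
      opt <- stats::nlminb(start, obj, lower = lo, upper = hi,
                           control = list(iter.max = 400))
      if (is.null(best) || opt$objective < best$objective) best <- opt
    }
    sse_total <- sse_total + best$objective
    par_rows[[ui]] <- stats::setNames(best$par, UNIT_PARS)
  }
  n <- nrow(data)
  sigma_hat <- sqrt(sse_total / n)
  dev <- n * log(2 * pi * sigma_hat^2) + n
  pars <- do.call(rbind, par_rows)
  list(deviance = dev, k = 5L * length(units), sigma = sigma_hat,
       params = tibble::tibble(label = units, tibble::as_tibble(pars)))
}
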