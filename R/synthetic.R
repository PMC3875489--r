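#' Diurnal driver curves for synthetic campaigns
#'
#' Smooth half-sine diurnal courses for the model drivers, peaking at solar
#' noon: scaled VPD `D(h) = D_max * sin(pi (h - 6) / 12)` (floored at 0.001),
#' net photosynthesis `A_n(h) = A_max * sin(pi (h - 6) / 12)` (floored at 0),
#' and intercellular CO2 drawn down with assimilation,
#' `C_i(h) = c_0 * (1 - 0.25 * A_n / A_max)`.
#'
#' @param hours integer hours of day to evaluate (default 7..18).
#' @param d_max peak scaled VPD, dimensionless, in (0, 0.1].
#' @param a_max peak net photosynthesis, umol m-2 s-1, in (0, 40].
#' @param c_0 reference CO2 mole fraction, umol mol-1.
#' @return A tibble with columns `hour, d, a_n, c_i`.
#' @export
#' @examples
#' diurnal_drivers(7:18, d_max = 0.04, a_max = 12)
diurnal_drivers <- function(hours = 7:18, d_max = 0.04, a_max = 12, c_0 = 370) {
  stopifnot(d_max > 0, d_max <= 0.1, a_max > 0, a_max <= 40)
  s <- sin(pi * (hours - 6) / 12)
  a_n <- pmax(a_max * s, 0)
  tibble::tibble(
    hour = as.integer(hours),
    d = pmax(d_max * s, 0.001),
    a_n = a_n,
    c_i = c_0 * (1 - 0.25 * a_n / a_max)
  )
}

#' Design of a synthetic gas-exchange study
#'
#' Describes a synthetic multi-observation diurnal campaign with the
#' statistical structure the hierarchical analysis assumes: observations
#' nested in functional groups, several diurnal days per observation with a
#' constant (latent) soil water potential per day, several leaves per hour,
#' and i.i.d. Gaussian observation noise on stomatal conductance truncated
#' at zero. The default true parameters are the published group estimates
#' ([pft_params()]), so synthetic data are field-realistic.
#'
#' @param groups functional groups to simulate.
#' @param n_obs_per_group observations (species x site) per group.
#' @param n_days diurnal days per observation.
#' @param hours hours of day measured.
#' @param n_leaves replicate leaves per hour.
#' @param true_params parameter tibble with one row per group (matched by
#'   `label`) or per observation.
#' @param psi_day_range interval (MPa) from which each day's latent soil
#'   water potential is drawn uniformly; within [-8, -0.01].
#' @param noise_sd SD of the Gaussian observation noise on `g_s`,
#'   mol m-2 s-1 (> 0).
#' @param d_max,a_max diurnal driver peaks, see [diurnal_drivers()].
#' @param param_jitter_cv optional lognormal coefficient of variation applied
#'   per observation to the group parameters (0 = all observations share the
#'   group values; 0.2 emulates the spread of observation-level estimates).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return A design list (class `"synthetic_design"`).
#' @export
synthetic_design <- function(groups = c("DCDS", "LEGM", "SUBS"),
                             n_obs_per_group = 1, n_days = 3, hours = 7:18,
                             n_leaves = 3, true_params = pft_params(groups),
                             psi_day_range = c(-3, -0.1), noise_sd = 0.1,
                             d_max = 0.04, a_max = 12,
                             param_jitter_cv = 0, seed = 1L) {
  stopifnot(noise_sd > 0,
            psi_day_range[1] >= -8, psi_day_range[2] <= -0.01,
            psi_day_range[1] < psi_day_range[2])
  structure(
    list(groups = groups, n_obs_per_group = n_obs_per_group, n_days = n_days,
         hours = hours, n_leaves = n_leaves, true_params = true_params,
         psi_day_range = psi_day_range, noise_sd = noise_sd,
         d_max = d_max, a_max = a_max, param_jitter_cv = param_jitter_cv,
         seed = as.integer(seed)),
    class = "synthetic_design")
}

# truncated-at-zero Gaussian noise via inverse CDF (exact, vectorized)
rnorm_trunc0 <- function(mu, sd) {
  lo <- stats::pnorm(0, mean = mu, sd = sd)
  u <- stats::runif(length(mu), min = lo, max = 1)
  stats::qnorm(u, mean = mu, sd = sd)
}

#' Generate a synthetic gas-exchange dataset with known truth
#'
#' For each observation, draws one latent soil water potential per day
#' (uniform on the design's `psi_day_range`), evaluates the forward model
#' ([solve_leaf()]) along the diurnal driver curves for each leaf, and adds
#' zero-truncated Gaussian noise to the modeled conductance. Returns both
#' the harmonized record table (the same layout [read_gas_exchange()]
#' produces) and the generating truth for recovery tests.
#'
#' @param design a [synthetic_design()].
#' @return A list with elements `records` (tibble: obs_id, species, pft,
#'   date, hour, leaf, gs_mol, an_umol, ci_umol, vpd_kpa, p_kpa, tleaf_c,
#'   gs_true), `truth` (list: `params` tibble per observation, `psi_day`
#'   tibble with obs_id/date/psi, `noise_sd`, `seed`).
#' @export
#' @examples
#' sim <- generate_dataset(synthetic_design(n_days = 1, hours = c(10, 12, 14),
#'                                          n_leaves = 1))
#' nrow(sim$records)
generate_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed)

  drv <- diurnal_drivers(design$hours, design$d_max, design$a_max,
                         c_0 = design$true_params$c_0[1])
  p_kpa <- 101.325
  obs_grid <- tidyr::expand_grid(pft = design$groups,
                                 rep = seq_len(design$n_obs_per_group))
  obs_grid$obs_id <- sprintf("%s_%02d", obs_grid$pft, obs_grid$rep)

  params_list <- vector("list", nrow(obs_grid))
  rec_list <- vector("list", nrow(obs_grid))
  psi_list <- vector("list", nrow(obs_grid))

  for (k in seq_len(nrow(obs_grid))) {
    grp <- obs_grid$pft[k]
    base <- if (nrow(design$true_params) == length(design$groups) ||
                "label" %in% names(design$true_params)) {
      i <- match(grp, design$true_params$label)
      if (is.na(i)) i <- k
      design$true_params[i, ]
    } else {
      design$true_params[k, ]
    }
    p <- base
    if (design$param_jitter_cv > 0) {
      sdlog <- sqrt(log(1 + design$param_jitter_cv^2))
      for (col in c("k_psi", "g_p", "pi_0", "k_i", "xi")) {
        p[[col]] <- p[[col]] * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
      }
      p$k_psi <- min(max(p$k_psi, 0.01), 1.5)
      p$pi_0 <- min(p$pi_0, 3)
    }
    p$label <- obs_grid$obs_id[k]
    params_list[[k]] <- p

    dates <- sprintf("2004-07-%02d", seq_len(design$n_days))
    psi_d <- stats::runif(design$n_days, design$psi_day_range[1],
                          design$psi_day_range[2])
    psi_list[[k]] <- tibble::tibble(obs_id = p$label, date = dates, psi = psi_d)

    day_grid <- tidyr::expand_grid(date = dates, leaf = sprintf("L%d", seq_len(design$n_leaves)),
                                   hour = drv$hour)
    day_grid <- dplyr::left_join(day_grid, drv, by = "hour")
    day_grid$psi <- psi_d[match(day_grid$date, dates)]
    sol <- solve_leaf(p, psi_soil = day_grid$psi, d = day_grid$d,
                      a_n = day_grid$a_n, c_i = day_grid$c_i)
    gs_obs <- rnorm_trunc0(sol$g_s, design$noise_sd)
    rec_list[[k]] <- tibble::tibble(
      obs_id = p$label, species = p$label, pft = grp,
      date = day_grid$date, hour = day_grid$hour, leaf = day_grid$leaf,
      gs_mol = gs_obs, an_umol = day_grid$a_n, ci_umol = day_grid$c_i,
      vpd_kpa = day_grid$d * p_kpa, p_kpa = p_kpa, tleaf_c = 30,
      gs_true = sol$g_s
    )
  }
  list(
    records = dplyr::bind_rows(rec_list),
    truth = list(params = dplyr::bind_rows(params_list),
                 psi_day = dplyr::bind_rows(psi_list),
                 noise_sd = design$noise_sd, seed = design$seed)
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a synthetic dataset to disk
#'
#' Emits one harmonized CSV per observation, a YAML manifest listing them,
#' and the generating truth as JSON, in the dialect [read_manifest()] reads.
#'
#' @param sim result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs <- split(sim$records, sim$records$obs_id)
  entries <- lapply(obs, function(tab) {
    f <- paste0(tab$obs_id[1], ".csv")
    readr::write_csv(tab[setdiff(names(tab), "gs_true")], file.path(dir, f),
                     progress = FALSE)
    list(obs_id = tab$obs_id[1], species = tab$species[1],
         pft = tab$pft[1], file = f)
  })
  yaml::write_yaml(list(observations = unname(entries)),
                   file.path(dir, "manifest.yaml"))
  truth <- sim$truth
  truth$params <- as.list(truth$params)
  truth$psi_day <- as.list(truth$psi_day)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a truth record written by [write_dataset()]
#' @param path `truth.json` file.
#' @return list with `params` and `psi_day` tibbles, `noise_sd`, `seed`.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$params <- tibble::as_tibble(raw$params)
  raw$psi_day <- tibble::as_tibble(raw$psi_day)
  raw
}
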