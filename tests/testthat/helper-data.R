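# Small in-code fixtures shared across tests.

# one-row parameter table for ad-hoc checks
demo_params <- function(label = "demo", k_psi = 0.5, g_p = 0.004,
                        c_lambda = 3.13, pi_0 = 1.8, k_i = 300, xi = 20) {
  stomatal_params(label, k_psi, g_p, c_lambda, pi_0, k_i, xi)
}

# a tiny harmonized record tibble with model-consistent predictions
make_records <- function(n = 3, obs_id = "A", psi = -0.5,
                         d = c(0.01, 0.02, 0.03)[seq_len(n)],
                         an = 6.5, params = demo_params(obs_id)) {
  rec <- tibble::tibble(
    obs_id = obs_id, species = obs_id, pft = "SUBS",
    date = "2004-07-01", hour = seq(10, by = 1, length.out = n),
    leaf = "L1",
    gs_mol = NA_real_, an_umol = an, ci_umol = 370,
    vpd_kpa = d * 101.325, p_kpa = 101.325, tleaf_c = 30
  )
  sol <- solve_leaf(params, psi_soil = psi, d = d, a_n = an)
  rec$gs_mol <- sol$g_s
  rec
}

psi_table <- function(obs_id = "A", date = "2004-07-01", psi = -0.5) {
  tibble::tibble(obs_id = obs_id, date = date, psi = psi)
}

# write a gas-exchange CSV in LI-6400 column names; returns the path
write_licor_csv <- function(df, dir = tempdir()) {
  path <- tempfile("gasx", tmpdir = dir, fileext = ".csv")
  readr::write_csv(df, path, progress = FALSE)
  path
}
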