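test_that("unit conversions match closed-form oracles", {
  # mmol -> mol is a plain rescale
  expect_equal(convert_units(250, "mmol_m2_s", "mol_m2_s"), 0.25)
  # molar resistance is the reciprocal of molar conductance
  expect_equal(convert_units(2.5, "m2_s_mol", "mol_m2_s"), 1 / 2.5)
  # velocity -> molar via ideal-gas molar density of air
  expect_equal(convert_units(0.01, "m_s", "mol_m2_s",
                             temp = 25, pressure = 101.325),
               0.01 * 101325 / (8.314 * 298.15), tolerance = 1e-10)
  expect_equal(convert_units(3.5, "hpa", "kpa"), 0.35)
  expect_equal(convert_units(3.5, "mbar", "kpa"), 0.35)
  expect_error(convert_units(1, "kpa", "mol_m2_s"), "unsupported")
  expect_error(convert_units(0.01, "m_s", "mol_m2_s"), "needs")
})

test_that("unit conversions are involutive to 10 significant digits", {
  cond_units <- c("mol_m2_s", "mmol_m2_s", "m2_s_mol", "m_s", "cm_s",
                  "s_m", "s_cm")
  for (a in cond_units) for (b in cond_units) {
    x <- 0.37
    back <- convert_units(convert_units(x, a, b, temp = 25, pressure = 101.325),
                          b, a, temp = 25, pressure = 101.325)
    expect_equal(back, x, tolerance = 1e-10,
                 label = paste("roundtrip", a, "->", b))
  }
  for (a in c("kpa", "hpa", "mbar")) for (b in c("kpa", "hpa", "mbar")) {
    expect_equal(convert_units(convert_units(2.2, a, b), b, a), 2.2,
                 tolerance = 1e-10)
  }
})

test_that("scaled VPD and the humidity identity behave", {
  expect_equal(scaled_vpd(0.3546, 101.325), 0.0035, tolerance = 1e-3)
  expect_equal(scaled_vpd(0, 101.325), 0)
  expect_equal(scaled_vpd(5.066, 101.325), 0.05, tolerance = 1e-3)
  expect_error(scaled_vpd(1, 0), "positive")

  # D = 0.0035 at 30 C, sea level is about 91% RH (Tetens)
  rh <- relative_humidity_from_d(0.0035, temp_c = 30, p_kpa = 101.325)
  expect_equal(rh, 1 - 0.0035 * 101.325 / (0.61078 * exp(17.27 * 30 / 267.3)),
               tolerance = 1e-12)
  expect_true(abs(rh - 0.91) < 0.01)
  expect_equal(relative_humidity_from_d(0, 25), 1)
  # demand beyond saturation clamps to zero with a warning
  expect_warning(rh0 <- relative_humidity_from_d(0.05, 30, 101.325), "clamped")
  expect_equal(rh0, 0)
  expect_error(relative_humidity_from_d(0.001, 80), "range")
})

test_that("gas-exchange tables read, harmonize and filter", {
  df <- tibble::tibble(Date = "2004-07-01", HHMMSS = c(103000, 113000, 123000),
                       Leaf = "L1", Cond = c(0.2, 0.3, 0.4),
                       Photo = 6.5, Ci = 300, VpdL = 1.2, Press = 101.3,
                       Tleaf = 30)
  path <- write_licor_csv(df)
  tab <- read_gas_exchange(path, obs_id = "o1", pft = "SUBS")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$gs_mol, c(0.2, 0.3, 0.4))
  expect_equal(tab$hour, c(10L, 11L, 12L))

  # a negative-VPD row is dropped with a reported count
  df_bad <- df
  df_bad$VpdL[2] <- -0.1
  expect_message(tab2 <- read_gas_exchange(write_licor_csv(df_bad),
                                           obs_id = "o1", pft = "SUBS"),
                 "dropped 1")
  expect_equal(nrow(tab2), 2)

  # resistance-dialect file: r = 2.5 m2 s mol-1 -> g_s = 0.4 mol m-2 s-1
  df_r <- df
  names(df_r)[names(df_r) == "Cond"] <- "Rst"
  df_r$Rst <- 2.5
  dia <- gas_exchange_dialect(gs = "Rst", gs_unit = "m2_s_mol")
  tab3 <- read_gas_exchange(write_licor_csv(df_r), obs_id = "o1",
                            pft = "SUBS", dialect = dia)
  expect_equal(tab3$gs_mol, rep(0.4, 3))

  # a missing mandatory column is a named format error
  expect_error(read_gas_exchange(write_licor_csv(df[, -4]),
                                 obs_id = "o1", pft = "SUBS"),
               "Cond")
  # all-invalid tables are an explicit empty-input error
  df_all_bad <- df
  df_all_bad$Press <- 5
  expect_error(
    suppressMessages(read_gas_exchange(write_licor_csv(df_all_bad),
                                       obs_id = "o1", pft = "SUBS")),
    "no valid records")
})

test_that("leaf-hour averaging means replicates, keys on leaf, idempotent", {
  rec <- make_records(n = 2, d = c(0.01, 0.01))
  rec$hour <- c(10L, 10L)
  rec$gs_mol <- c(0.2, 0.4)
  out <- average_by_leaf_hour(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$gs_mol, 0.3)
  # idempotence
  expect_equal(average_by_leaf_hour(out)$gs_mol, out$gs_mol)
  # three leaves in one hour stay three records
  rec3 <- make_records(n = 3, d = rep(0.01, 3))
  rec3$hour <- 10L
  rec3$leaf <- c("L1", "L2", "L3")
  expect_equal(nrow(average_by_leaf_hour(rec3)), 3)
  # balanced groups preserve the overall mean of every numeric field
  rec4 <- dplyr::bind_rows(rec, rec)
  rec4$leaf <- rep(c("L1", "L2"), each = 2)
  out4 <- average_by_leaf_hour(rec4)
  expect_equal(mean(out4$gs_mol), mean(rec4$gs_mol))
  expect_error(average_by_leaf_hour(rec[0, ]), "empty")
})

test_that("manifest round trip binds observations with metadata", {
  dir <- file.path(tempdir(), "manif-test")
  dir.create(dir, showWarnings = FALSE)
  rec <- make_records(n = 3)
  for (id in c("obsA", "obsB")) {
    r <- rec
    r$obs_id <- id
    readr::write_csv(r, file.path(dir, paste0(id, ".csv")), progress = FALSE)
  }
  yaml::write_yaml(list(observations = list(
    list(obs_id = "obsA", species = "Artemisia frigida", pft = "SUBS",
         file = "obsA.csv"),
    list(obs_id = "obsB", species = "Caragana microphylla", pft = "LEGM",
         file = "obsB.csv"))), file.path(dir, "manifest.yaml"))
  all <- read_manifest(file.path(dir, "manifest.yaml"))
  expect_equal(nrow(all), 6)
  expect_setequal(unique(all$pft), c("SUBS", "LEGM"))
  expect_equal(all$species[all$obs_id == "obsA"][1], "Artemisia frigida")
})
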