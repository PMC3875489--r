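#' Column dialects for gas-exchange tables
#'
#' A dialect maps the columns of an instrument export onto the canonical
#' record fields and states which unit the conductance column is in.
#' `licor6400_dialect()` matches standard LI-6400 text exports; resistance
#' instruments (e.g. porometers reporting m2 s mol-1 or s cm-1) are handled
#' by setting `gs_unit` to the resistance tag, and the reader converts to
#' molar conductance via [convert_units()].
#'
#' @param gs,an,ci,vpd,p,tleaf,date,hour,leaf column names in the file;
#'   `ci` and `tleaf` may be `NA` (absent).
#' @param gs_unit unit tag of the conductance/resistance column.
#' @param vpd_unit,p_unit pressure unit tags.
#' @return a named list usable as the `dialect` argument of
#'   [read_gas_exchange()].
#' @export
gas_exchange_dialect <- function(gs = "Cond", an = "Photo", ci = "Ci",
                                 vpd = "VpdL", p = "Press", tleaf = "Tleaf",
                                 date = "Date", hour = "HHMMSS", leaf = "Leaf",
                                 gs_unit = "mol_m2_s",
                                 vpd_unit = "kpa", p_unit = "kpa") {
  list(gs = gs, an = an, ci = ci, vpd = vpd, p = p, tleaf = tleaf,
       date = date, hour = hour, leaf = leaf,
       gs_unit = gs_unit, vpd_unit = vpd_unit, p_unit = p_unit)
}

#' @rdname gas_exchange_dialect
#' @export
licor6400_dialect <- function() gas_exchange_dialect()

#' @rdname gas_exchange_dialect
#' @export
canonical_dialect <- function() {
  gas_exchange_dialect(gs = "gs_mol", an = "an_umol", ci = "ci_umol",
                       vpd = "vpd_kpa", p = "p_kpa", tleaf = "tleaf_c",
                       date = "date", hour = "hour", leaf = "leaf")
}

parse_hour <- function(x) {
  if (is.numeric(x)) {
    # HHMMSS integers (e.g. 103015) vs plain hours
    return(ifelse(x > 24, x %/% 10000, floor(x)))
  }
  x <- as.character(x)
  has_colon <- grepl(":", x, fixed = TRUE)
  out <- numeric(length(x))
  out[has_colon] <- as.numeric(sub(":.*$", "", x[has_colon]))
  rest <- !has_colon
  num <- suppressWarnings(as.numeric(x[rest]))
  out[rest] <- ifelse(num > 24, num %/% 10000, floor(num))
  out
}

#' Read one diurnal gas-exchange table
#'
#' Reads a CSV export for a single species-by-site observation, renames
#' columns through a dialect, harmonizes all units to the molar convention
#' (conductance mol m-2 s-1, pressures kPa), and drops records that violate
#' the physical sanity bounds (negative conductance or VPD, assimilation
#' outside [-5, 60] umol m-2 s-1, pressure outside [50, 110] kPa, scaled
#' VPD above 0.2), reporting how many rows were dropped.
#'
#' @param path CSV file (UTF-8, header row).
#' @param obs_id,species,pft observation metadata; `pft` one of
#'   `"DCDS"`, `"LEGM"`, `"SUBS"`.
#' @param dialect column mapping, see [gas_exchange_dialect()].
#' @return A tibble of harmonized leaf-hour records with columns
#'   `obs_id, species, pft, date, hour, leaf, gs_mol, an_umol, ci_umol,
#'   vpd_kpa, p_kpa, tleaf_c`.
#' @export
read_gas_exchange <- function(path, obs_id, species = obs_id,
                              pft = c("DCDS", "LEGM", "SUBS"),
                              dialect = licor6400_dialect()) {
  pft <- match.arg(pft)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  need <- c("gs", "an", "vpd", "p", "date", "hour", "leaf")
  for (field in need) {
    col <- dialect[[field]]
    if (is.na(col) || !col %in% names(raw)) {
      stop("mandatory column for '", field, "' (", col, ") not found in ", path,
           call. = FALSE)
    }
  }
  grab <- function(field) {
    col <- dialect[[field]]
    if (is.null(col) || is.na(col) || !col %in% names(raw)) {
      rep(NA_real_, nrow(raw))
    } else {
      raw[[col]]
    }
  }

  tleaf <- as.numeric(grab("tleaf"))
  p_kpa <- convert_units(as.numeric(grab("p")), dialect$p_unit, "kpa")
  temp_for_gas <- ifelse(is.na(tleaf), 25, tleaf)
  gs <- as.numeric(grab("gs"))
  if (!identical(dialect$gs_unit, "mol_m2_s")) {
    gs <- convert_units(gs, dialect$gs_unit, "mol_m2_s",
                        temp = temp_for_gas, pressure = p_kpa)
  }
  out <- tibble::tibble(
    obs_id = as.character(obs_id), species = as.character(species), pft = pft,
    date = as.character(grab("date")),
    hour = as.integer(parse_hour(raw[[dialect$hour]])),
    leaf = as.character(raw[[dialect$leaf]]),
    gs_mol = gs,
    an_umol = as.numeric(grab("an")),
    ci_umol = as.numeric(grab("ci")),
    vpd_kpa = convert_units(as.numeric(grab("vpd")), dialect$vpd_unit, "kpa"),
    p_kpa = p_kpa,
    tleaf_c = tleaf
  )
  out <- drop_invalid_records(out, context = path)
  if (nrow(out) == 0) stop("no valid records left in ", path, call. = FALSE)
  out
}

drop_invalid_records <- function(data, context = "input") {
  ok <- with(data,
    !is.na(gs_mol) & gs_mol >= 0 &
    !is.na(an_umol) & an_umol >= -5 & an_umol <= 60 &
    !is.na(vpd_kpa) & vpd_kpa >= 0 &
    !is.na(p_kpa) & p_kpa >= 50 & p_kpa <= 110 &
    vpd_kpa / p_kpa <= 0.2
  )
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(context, ": dropped ", n_bad, " record(s) violating sanity bounds")
  }
  data[ok, , drop = FALSE]
}

#' Average replicate records per leaf and hour
#'
#' Diurnal campaigns log several replicates on the same leaf within an hour;
#' to avoid treating them as independent, all numeric fields are
#' arithmetically averaged per (observation, date, hour, leaf). Averaging is
#' a mandatory preparation step before fitting. The operation is idempotent.
#'
#' @param data a harmonized record tibble from [read_gas_exchange()].
#' @return A tibble with one row per (obs_id, date, hour, leaf).
#' @export
average_by_leaf_hour <- function(data) {
  if (nrow(data) == 0) stop("empty table", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::any_of(
      c("obs_id", "species", "pft", "date", "hour", "leaf")))),
    dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
}

#' Write a harmonized gas-exchange table
#'
#' @param data a harmonized record tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A YAML manifest lists the observations of a dataset: each entry has
#' `obs_id`, `species`, `pft` and `file` (CSV path relative to the manifest).
#' All tables are read, harmonized and bound into one record tibble.
#'
#' @param path YAML manifest file.
#' @param dialect column mapping applied to every listed file.
#' @return A single record tibble covering all observations.
#' @export
read_manifest <- function(path, dialect = canonical_dialect()) {
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  entries <- if (!is.null(man$observations)) man$observations else man
  purrr::map_dfr(entries, function(e) {
    read_gas_exchange(file.path(base, e$file), obs_id = e$obs_id,
                      species = e$species %||% e$obs_id, pft = e$pft,
                      dialect = dialect)
  })
}
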