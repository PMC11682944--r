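#' Default compound specifications for the residue simulator
#'
#' One row per pesticide compound with the lognormal concentration model used
#' by [generate_residues()]: per-matrix log-scale location and spread
#' (concentrations in µg/kg are positive and right-skewed, so a lognormal is
#' the natural model), a per-record detection probability, a far-site
#' concentration multiplier, and analytical detection/quantification limits.
#' The two neonicotinoids clothianidin and thiamethoxam carry multipliers
#' above 1 so that apiaries far from highbush blueberry show the elevated
#' concentrations reported for this system; all other compounds use
#' multiplier 1.
#'
#' @return A tibble with one row per compound and columns `compound`,
#'   `detection_prob`, `log_mean_pollen`, `log_sd_pollen`, `log_mean_nectar`,
#'   `log_sd_nectar`, `far_site_multiplier`, `lod_ug_per_kg`, `loq_ug_per_kg`
#'   and a list-column `detect_sites` (NULL entries mean random detection; a
#'   character vector pins detection to exactly those sites, used to plant
#'   known exceedance patterns for validation).
#' @export
default_synthetic_compounds <- function() {
  # detection_instances: how often each compound was detected across the
  # 160 pooled apiary samples of this system (20 sites x 2 years x 2 time
  # points x 2 matrices); detection_prob = instances / 160
  spec <- tibble::tribble(
    ~compound,             ~detection_instances, ~med_pollen, ~med_nectar, ~far_site_multiplier,
    "boscalid",            33,                   20.0,        5.0,         1,
    "chlorantraniliprole",  1,                    2.0,        0.5,         1,
    "clothianidin",         6,                    1.0,        0.6,         3,
    "coumaphos",            1,                    5.0,        1.0,         1,
    "difenoconazole",       3,                    3.0,        1.0,         1,
    "dimethoate",           4,                    2.0,        0.8,         1,
    "fenhexamid",           1,                   10.0,        2.0,         1,
    "flonicamid",           4,                    4.0,        1.5,         1,
    "fluopyram",           47,                   15.0,        4.0,         1,
    "flupyradifurone",     50,                   12.0,        6.0,         1,
    "imidacloprid",        30,                    1.5,        0.7,         1,
    "linuron",             21,                    8.0,        2.0,         1,
    "mandipropamid",        1,                    3.0,        1.0,         1,
    "metconazole",         22,                    6.0,        1.5,         1,
    "napropamide",          1,                    4.0,        1.0,         1,
    "novaluron",            2,                    5.0,        1.0,         1,
    "omethoate",            1,                    1.0,        0.4,         1,
    "pyraclostrobin",      33,                   18.0,        4.0,         1,
    "pyrimethanil",        37,                   25.0,        6.0,         1,
    "thiamethoxam",        15,                    1.8,        1.5,         2.5
  )
  spec$detection_prob <- spec$detection_instances / 160
  low_lod <- c("clothianidin", "thiamethoxam", "imidacloprid",
               "dimethoate", "omethoate")
  tibble::tibble(
    compound = spec$compound,
    detection_prob = spec$detection_prob,
    log_mean_pollen = log(spec$med_pollen),
    log_sd_pollen = 0.9,
    log_mean_nectar = log(spec$med_nectar),
    log_sd_nectar = 0.9,
    far_site_multiplier = spec$far_site_multiplier,
    lod_ug_per_kg = ifelse(spec$compound %in% low_lod, 0.05, 0.5),
    loq_ug_per_kg = ifelse(spec$compound %in% low_lod, 0.15, 1.5),
    detect_sites = vector("list", nrow(spec))
  )
}

#' Build a simulator configuration
#'
#' Describes one simulated field study: apiaries near (< 1.5 km) and far
#' (> 1.5 km) from highbush blueberry, sampled at two time points (T2, during
#' bloom; T3, end of bloom) in each of two study years, one pooled
#' apiary-level sample per site and matrix (pollen, nectar). The defaults
#' mirror that design: 10 near and 10 far sites, time points T2/T3, years
#' 2020/2021, the 20-compound specification of
#' [default_synthetic_compounds()].
#'
#' @param n_near_sites,n_far_sites number of apiaries in each proximity class
#'   (each at least 1).
#' @param time_points character vector of sampling time point labels.
#' @param years vector of study year labels.
#' @param compounds compound specification tibble (see
#'   [default_synthetic_compounds()] for the column contract).
#' @param seed integer seed; the generator is fully deterministic for a fixed
#'   configuration and seed.
#' @return A validated list of class `beecotox_synthetic_config`.
#' @export
synthetic_config <- function(n_near_sites = 10,
                             n_far_sites = 10,
                             time_points = c("T2", "T3"),
                             years = c(2020, 2021),
                             compounds = default_synthetic_compounds(),
                             seed = 20210615) {
  cfg <- structure(
    list(n_near_sites = n_near_sites, n_far_sites = n_far_sites,
         time_points = time_points, years = years,
         compounds = tibble::as_tibble(compounds), seed = seed),
    class = "beecotox_synthetic_config"
  )
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (!is.numeric(cfg$n_near_sites) || length(cfg$n_near_sites) != 1 ||
      cfg$n_near_sites < 1) {
    abort_config("n_near_sites", "must be a single count >= 1")
  }
  if (!is.numeric(cfg$n_far_sites) || length(cfg$n_far_sites) != 1 ||
      cfg$n_far_sites < 1) {
    abort_config("n_far_sites", "must be a single count >= 1")
  }
  if (length(cfg$time_points) < 1) abort_config("time_points", "must be non-empty")
  if (length(cfg$years) < 1) abort_config("years", "must be non-empty")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    abort_config("seed", "must be a single integer")
  }
  cmp <- cfg$compounds
  needed <- c("compound", "detection_prob", "log_mean_pollen", "log_sd_pollen",
              "log_mean_nectar", "log_sd_nectar", "far_site_multiplier",
              "lod_ug_per_kg", "loq_ug_per_kg")
  miss <- setdiff(needed, names(cmp))
  if (length(miss) > 0) {
    abort_config("compounds", sprintf("missing column(s): %s",
                                      paste(miss, collapse = ", ")))
  }
  if (!"detect_sites" %in% names(cmp)) {
    cmp$detect_sites <- vector("list", nrow(cmp))
    cfg$compounds <- cmp
  }
  if (nrow(cmp) < 1) abort_config("compounds", "must have at least one row")
  if (anyDuplicated(cmp$compound)) abort_config("compounds", "has duplicate names")
  if (any(cmp$detection_prob < 0 | cmp$detection_prob > 1)) {
    abort_config("detection_prob", "must lie in [0, 1]")
  }
  if (any(cmp$far_site_multiplier < 0)) {
    abort_config("far_site_multiplier", "must be >= 0")
  }
  if (any(cmp$log_sd_pollen < 0) || any(cmp$log_sd_nectar < 0)) {
    abort_config("log_sd", "must be >= 0")
  }
  if (any(cmp$lod_ug_per_kg > cmp$loq_ug_per_kg)) {
    abort_config("lod_ug_per_kg", "must be <= loq_ug_per_kg for every compound")
  }
  if (any(cmp$lod_ug_per_kg < 0)) abort_config("lod_ug_per_kg", "must be >= 0")
  cfg
}

#' @export
print.beecotox_synthetic_config <- function(x, ...) {
  cat("<beecotox synthetic study configuration>\n")
  cat(sprintf("  sites:       %d near + %d far from highbush blueberry\n",
              x$n_near_sites, x$n_far_sites))
  cat(sprintf("  time points: %s\n", paste(x$time_points, collapse = ", ")))
  cat(sprintf("  years:       %s\n", paste(x$years, collapse = ", ")))
  cat(sprintf("  compounds:   %d\n", nrow(x$compounds)))
  cat(sprintf("  seed:        %s\n", format(x$seed)))
  invisible(x)
}

#' Simulate a censored residue table
#'
#' Draws one pooled apiary-level residue record per site x year x time point x
#' matrix x compound. Each record is a non-detect with probability
#' `1 - detection_prob`; otherwise the concentration is lognormal with the
#' compound's per-matrix parameters, multiplied by `far_site_multiplier` at
#' far sites, then censored against the analytical limits: values below the
#' limit of detection (LOD) are stored as 0 and flagged `below_lod`, values
#' between LOD and the limit of quantification (LOQ) keep their value but are
#' flagged `below_loq`, and values at or above LOQ are flagged `detected`.
#' Compounds with a non-NULL `detect_sites` entry are instead detected
#' deterministically at exactly those sites, at the compound's per-matrix
#' median concentration (times the far multiplier), and are non-detects
#' everywhere else — a hook for planting known exceedance patterns.
#'
#' Output row order and all draws are fixed by the configuration and its
#' seed, so repeated runs are byte-identical.
#'
#' @param config a configuration from [synthetic_config()].
#' @return A tibble of residue records with columns `site_id`, `proximity`,
#'   `year`, `time_point`, `matrix`, `compound`, `concentration_ug_per_kg`,
#'   `censoring`.
#' @examples
#' cfg <- synthetic_config(n_near_sites = 2, n_far_sites = 2, seed = 1)
#' res <- generate_residues(cfg)
#' head(res)
#' @export
generate_residues <- function(config) {
  config <- validate_synthetic_config(config)
  cmp <- config$compounds

  sites <- tibble::tibble(
    site_id = c(sprintf("near_%02d", seq_len(config$n_near_sites)),
                sprintf("far_%02d", seq_len(config$n_far_sites))),
    proximity = c(rep("near", config$n_near_sites),
                  rep("far", config$n_far_sites))
  )

  grid <- tidyr::expand_grid(
    compound = cmp$compound,
    sites,
    year = config$years,
    time_point = config$time_points,
    matrix = c("pollen", "nectar")
  )
  grid <- dplyr::left_join(grid, cmp, by = "compound")

  set.seed(as.integer(config$seed %% .Machine$integer.max))
  n <- nrow(grid)
  u_detect <- stats::runif(n)
  z <- stats::rnorm(n)

  log_mean <- ifelse(grid$matrix == "pollen",
                     grid$log_mean_pollen, grid$log_mean_nectar)
  log_sd <- ifelse(grid$matrix == "pollen",
                   grid$log_sd_pollen, grid$log_sd_nectar)
  mult <- ifelse(grid$proximity == "far", grid$far_site_multiplier, 1)

  pinned <- !vapply(grid$detect_sites, is.null, logical(1))
  detected <- ifelse(
    pinned,
    mapply(function(sites, id) id %in% sites, grid$detect_sites, grid$site_id),
    u_detect < grid$detection_prob
  )
  conc <- ifelse(
    pinned,
    exp(log_mean) * mult,             # deterministic planted concentration
    exp(log_mean + log_sd * z) * mult
  )
  conc <- ifelse(detected, conc, 0)

  censoring <- dplyr::case_when(
    !detected | conc < grid$lod_ug_per_kg ~ "below_lod",
    conc < grid$loq_ug_per_kg ~ "below_loq",
    TRUE ~ "detected"
  )
  conc[censoring == "below_lod"] <- 0

  tibble::tibble(
    site_id = grid$site_id,
    proximity = grid$proximity,
    year = grid$year,
    time_point = grid$time_point,
    matrix = grid$matrix,
    compound = grid$compound,
    concentration_ug_per_kg = conc,
    censoring = censoring
  )
}

#' Read and write residue tables
#'
#' Residue CSVs carry the documented header `site_id, proximity, year,
#' time_point, matrix, compound, concentration_ug_per_kg, censoring`.
#' Concentrations are µg of active ingredient per kg of matrix; non-detects
#' are stored as 0 with censoring flag `below_lod`.
#'
#' @param residues a residue tibble (as produced by [generate_residues()]).
#' @param path file path.
#' @return `read_residue_csv()` returns a validated tibble;
#'   `write_residue_csv()` returns `path` invisibly.
#' @export
write_residue_csv <- function(residues, path) {
  residues <- validate_residues(residues)
  utils::write.csv(residues, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_residue_csv
#' @export
read_residue_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("cannot read residue table: no file at '%s'", path),
                 class = "beecotox_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_residues(tibble::as_tibble(df))
}

#' Validate a residue table
#'
#' Checks the column contract, enum values, non-negative concentrations and
#' consistency of censoring flags (a `below_lod` record must store 0).
#'
#' @param residues a data frame of residue records.
#' @return The validated tibble.
#' @export
validate_residues <- function(residues) {
  residues <- tibble::as_tibble(residues)
  needed <- c("site_id", "proximity", "year", "time_point", "matrix",
              "compound", "concentration_ug_per_kg", "censoring")
  miss <- setdiff(needed, names(residues))
  if (length(miss) > 0) {
    abort_validation(sprintf("residue table is missing column(s): %s",
                             paste(miss, collapse = ", ")))
  }
  if (!all(residues$proximity %in% c("near", "far"))) {
    abort_validation("proximity must be 'near' or 'far'")
  }
  if (!all(residues$matrix %in% c("pollen", "nectar"))) {
    abort_validation("matrix must be 'pollen' or 'nectar'")
  }
  if (!all(residues$censoring %in% c("detected", "below_loq", "below_lod"))) {
    abort_validation("censoring must be detected, below_loq or below_lod")
  }
  bad <- which(is.na(residues$concentration_ug_per_kg) |
                 residues$concentration_ug_per_kg < 0)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "negative or missing concentration in residue row(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(residues$censoring == "below_lod" &
                 residues$concentration_ug_per_kg != 0)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "below_lod records must store concentration 0; offending row(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  residues
}
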