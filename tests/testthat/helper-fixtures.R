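# Shared fixture builders and the independent brute-force RQ oracle.

residue_row <- function(site_id, matrix, compound, conc,
                        proximity = "near", year = 2021, time_point = "T2",
                        censoring = if (conc == 0) "below_lod" else "detected") {
  tibble::tibble(site_id = site_id, proximity = proximity, year = year,
                 time_point = time_point, matrix = matrix,
                 compound = compound, concentration_ug_per_kg = conc,
                 censoring = censoring)
}

tox_row <- function(compound, ld50 = NA, lc50 = NA, ldd50 = NA) {
  tibble::tibble(compound = compound,
                 acute_oral_ld50_ug_per_bee = ld50,
                 chronic_lc50_ug_per_bee_day = lc50,
                 chronic_ldd50_ug_per_bee_day = ldd50,
                 source_note = "test fixture")
}

# Brute-force per-record recomputation of site RQs: nested loops and plain
# arithmetic, independent of the vectorised implementation. Non-detects
# contribute zero; chronic endpoint is min(LC50, LDD50).
brute_force_site_rqs <- function(residues, tox,
                                 nectar_intake = 140e-6,
                                 pollen_intake = 9.6e-6) {
  keys <- unique(residues[, c("site_id", "year", "time_point", "compound")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- residues[residues$site_id == k$site_id &
                      residues$year == k$year &
                      residues$time_point == k$time_point &
                      residues$compound == k$compound, ]
    if (!any(sub$censoring != "below_lod")) next
    nectar <- 0; pollen <- 0
    for (j in seq_len(nrow(sub))) {
      if (sub$matrix[j] == "nectar") nectar <- sub$concentration_ug_per_kg[j]
      if (sub$matrix[j] == "pollen") pollen <- sub$concentration_ug_per_kg[j]
    }
    tr <- tox[tox$compound == k$compound, ]
    if (nrow(tr) == 0 || is.na(tr$acute_oral_ld50_ug_per_bee)) next
    intake <- nectar * nectar_intake + pollen * pollen_intake
    rqs <- data.frame(kind = "acute",
                      rq = intake / tr$acute_oral_ld50_ug_per_bee)
    chronic <- suppressWarnings(min(tr$chronic_lc50_ug_per_bee_day,
                                    tr$chronic_ldd50_ug_per_bee_day,
                                    na.rm = TRUE))
    if (is.finite(chronic)) {
      rqs <- rbind(rqs, data.frame(kind = "chronic", rq = intake / chronic))
    }
    rqs$site_id <- k$site_id; rqs$year <- k$year
    rqs$time_point <- k$time_point; rqs$compound <- k$compound
    out[[length(out) + 1]] <- rqs
  }
  do.call(rbind, out)
}

# Config that plants chronic exceedances at an exact set of sites: the
# thiamethoxam and clothianidin planted concentrations exceed the chronic
# level of concern wherever they are detected.
planted_exceedance_config <- function(seed = 42) {
  thia_sites <- c(sprintf("near_%02d", 1:5), sprintf("far_%02d", 1:3))
  clo_sites <- c("near_01", "far_01", "far_02")
  cmp <- beecotox::default_synthetic_compounds()
  cmp$detect_sites[[which(cmp$compound == "thiamethoxam")]] <- thia_sites
  cmp$detect_sites[[which(cmp$compound == "clothianidin")]] <- clo_sites
  list(
    config = beecotox::synthetic_config(compounds = cmp, seed = seed),
    thia_sites = thia_sites,
    clo_sites = clo_sites
  )
}
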