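#' Packaged toxicity reference table (synthetic placeholder endpoints)
#'
#' Returns the per-compound toxicity endpoints used to convert dietary
#' pesticide intake into risk quotients: the acute oral LD50 (µg active
#' ingredient per bee, single exposure) and, where available, chronic 10-day
#' oral LC50 and/or LDD50 endpoints (µg per bee per day). The table covers the
#' 20 pesticide compounds detected in pollen and nectar of colonies placed
#' around highbush blueberry in the Fraser Valley; chronic endpoints are
#' provided for the two neonicotinoids (clothianidin, thiamethoxam) for which
#' chronic risk is typically assessed.
#'
#' The endpoint values are synthetic placeholders at realistic orders of
#' magnitude, not literature values: real analyses must substitute a
#' user-supplied table via [read_toxicity_csv()].
#'
#' @return A tibble with columns `compound`, `acute_oral_ld50_ug_per_bee`,
#'   `chronic_lc50_ug_per_bee_day`, `chronic_ldd50_ug_per_bee_day`,
#'   `source_note`.
#' @seealso [read_toxicity_csv()], [compute_site_rqs()]
#' @examples
#' tox <- default_toxicity_reference()
#' tox[tox$compound == "thiamethoxam", ]
#' @export
default_toxicity_reference <- function() {
  path <- system.file("extdata", "toxicity_reference_synthetic.csv",
                      package = "beecotox", mustWork = TRUE)
  read_toxicity_csv(path)
}

#' Read a toxicity reference table from CSV
#'
#' The CSV must carry the columns `compound`, `acute_oral_ld50_ug_per_bee`,
#' `chronic_lc50_ug_per_bee_day`, `chronic_ldd50_ug_per_bee_day` and
#' optionally `source_note`. Missing endpoints are encoded as `NA`. Every
#' compound must have at least one endpoint, and all present endpoints must be
#' strictly positive.
#'
#' @param path path to a CSV file.
#' @return A validated tibble of toxicity endpoints.
#' @export
read_toxicity_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("cannot read toxicity table: no file at '%s'", path),
                 class = "beecotox_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_toxicity_reference(tibble::as_tibble(df))
}

#' Validate a toxicity reference table
#'
#' @param tox a data frame of toxicity endpoints (see [read_toxicity_csv()]
#'   for the column contract).
#' @return The table, as a tibble, invisibly unchanged apart from class.
#' @export
validate_toxicity_reference <- function(tox) {
  tox <- tibble::as_tibble(tox)
  required <- c("compound", "acute_oral_ld50_ug_per_bee",
                "chronic_lc50_ug_per_bee_day", "chronic_ldd50_ug_per_bee_day")
  missing_cols <- setdiff(required, names(tox))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("toxicity table is missing column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  if (!"source_note" %in% names(tox)) tox$source_note <- NA_character_
  if (anyDuplicated(tox$compound)) {
    abort_validation("toxicity table has duplicated compound rows")
  }
  endpoints <- as.matrix(tox[, required[-1]])
  if (any(rowSums(!is.na(endpoints)) == 0)) {
    bad <- tox$compound[rowSums(!is.na(endpoints)) == 0]
    abort_validation(sprintf("no toxicity endpoint present for compound(s): %s",
                             paste(bad, collapse = ", ")))
  }
  if (any(endpoints <= 0, na.rm = TRUE)) {
    abort_validation("toxicity endpoints must be strictly positive")
  }
  tox
}

# chronic endpoint per compound under a selection policy: the default takes
# the smaller of LC50/LDD50 (more conservative, larger RQ); NA when neither
# endpoint exists
chronic_endpoint <- function(tox_row, policy = c("min", "lc50", "ldd50")) {
  policy <- match.arg(policy)
  lc <- tox_row$chronic_lc50_ug_per_bee_day
  ldd <- tox_row$chronic_ldd50_ug_per_bee_day
  pick <- switch(policy,
    min   = suppressWarnings(pmin(lc, ldd, na.rm = TRUE)),
    lc50  = lc,
    ldd50 = ldd
  )
  used <- switch(policy,
    min = dplyr::case_when(
      is.na(lc) & is.na(ldd) ~ NA_character_,
      is.na(ldd) | (!is.na(lc) & lc <= ldd) ~ "lc50",
      TRUE ~ "ldd50"
    ),
    lc50  = ifelse(is.na(lc), NA_character_, "lc50"),
    ldd50 = ifelse(is.na(ldd), NA_character_, "ldd50")
  )
  pick[is.infinite(pick)] <- NA_real_
  list(value = pick, used = used)
}
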