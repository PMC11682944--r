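#' Daily pollen and nectar consumption constants
#'
#' Adult honey bees are assumed to consume 140 mg of nectar and 9.6 mg of
#' pollen per day; expressed in kg/bee/day these are the factors that convert
#' a residue concentration in µg/kg of matrix into a dietary dose in µg/bee.
#'
#' @param nectar_intake_kg daily nectar consumption, kg/bee/day.
#' @param pollen_intake_kg daily pollen consumption, kg/bee/day.
#' @return A list of class `beecotox_consumption` with both intakes.
#' @export
consumption_constants <- function(nectar_intake_kg = 140e-6,
                                  pollen_intake_kg = 9.6e-6) {
  if (nectar_intake_kg <= 0 || pollen_intake_kg <= 0) {
    abort_validation("consumption constants must be strictly positive")
  }
  structure(list(nectar_intake_kg = nectar_intake_kg,
                 pollen_intake_kg = pollen_intake_kg),
            class = "beecotox_consumption")
}

#' Regulatory risk-quotient thresholds (levels of concern)
#'
#' Acute oral exposure thresholds for adult honey bees are RQ = 0.4 (derived
#' from laboratory cage studies; joint PMRA-EPA-CALDPR guidance) and RQ = 0.2
#' (derived from field-colony studies, as used by EFSA); the EFSA chronic
#' oral exposure threshold is RQ = 0.03. Exceedance is strict (`rq >
#' threshold`): a quotient exactly at a level of concern is reported as a
#' non-exceedance.
#'
#' @param acute_cage,acute_field,chronic dimensionless RQ thresholds; must
#'   satisfy `chronic < acute_field < acute_cage`.
#' @return A list of class `beecotox_thresholds`.
#' @export
rq_thresholds <- function(acute_cage = 0.4, acute_field = 0.2,
                          chronic = 0.03) {
  if (!(chronic < acute_field && acute_field < acute_cage)) {
    abort_validation("thresholds must satisfy chronic < acute_field < acute_cage")
  }
  structure(list(acute_cage = acute_cage, acute_field = acute_field,
                 chronic = chronic),
            class = "beecotox_thresholds")
}

#' Acute dietary risk quotient
#'
#' The acute RQ relates the estimated daily dietary intake of a pesticide to
#' its acute oral median lethal dose:
#' \deqn{RQ_{acute} = \frac{C_{nectar} \times I_{nectar} + C_{pollen} \times
#'   I_{pollen}}{LD_{50}}}
#' with concentrations in µg/kg, intakes in kg/bee/day and the LD50 in
#' µg/bee. RQ = 1 means the daily intake equals the dose lethal to half a
#' test population. The quotient is linear (degree-1 homogeneous) in the two
#' residues and zero exactly when both residues are zero.
#'
#' @param nectar_residue,pollen_residue residue concentration, µg/kg (>= 0;
#'   0 encodes a non-detect). Vectorised.
#' @param ld50 acute oral LD50, µg/bee (> 0).
#' @param constants a [consumption_constants()] object.
#' @param compound compound label used in error messages.
#' @return dimensionless RQ (>= 0).
#' @examples
#' compute_rq_acute(1000, 0, ld50 = 0.14) # 1
#' @export
compute_rq_acute <- function(nectar_residue, pollen_residue, ld50,
                             constants = consumption_constants(),
                             compound = "<compound>") {
  rq_numerator(nectar_residue, pollen_residue, constants) /
    check_endpoint(ld50, compound, "acute oral LD50")
}

#' Chronic dietary risk quotient
#'
#' Same daily-intake numerator as [compute_rq_acute()], divided by a chronic
#' 10-day oral endpoint (LC50 or LDD50, µg/bee/day).
#'
#' @inheritParams compute_rq_acute
#' @param chronic_endpoint chronic 10-day oral LC50 or LDD50, µg/bee/day (> 0).
#' @return dimensionless RQ (>= 0).
#' @export
compute_rq_chronic <- function(nectar_residue, pollen_residue,
                               chronic_endpoint,
                               constants = consumption_constants(),
                               compound = "<compound>") {
  rq_numerator(nectar_residue, pollen_residue, constants) /
    check_endpoint(chronic_endpoint, compound, "chronic endpoint")
}

rq_numerator <- function(nectar_residue, pollen_residue, constants) {
  if (any(nectar_residue < 0, na.rm = TRUE) ||
      any(pollen_residue < 0, na.rm = TRUE)) {
    abort_validation("residue concentrations must be >= 0")
  }
  nectar_residue * constants$nectar_intake_kg +
    pollen_residue * constants$pollen_intake_kg
}

check_endpoint <- function(x, compound, what) {
  if (any(is.na(x)) || any(x <= 0)) {
    rlang::abort(
      sprintf("%s for compound '%s' is missing or non-positive", what, compound),
      class = "beecotox_toxicity_error"
    )
  }
  x
}

#' Per-compound site-level risk quotients
#'
#' For every (site, year, time point, compound) with at least one detection
#' (a record flagged `detected` or `below_loq` in either matrix) this
#' computes an acute RQ from the compound's LD50 and, when the compound has a
#' chronic endpoint, a chronic RQ. A matrix with no record, or a non-detect,
#' contributes residue 0. Detected compounds with no acute endpoint are not
#' an error: they are reported in the `skipped` attribute and omitted from
#' the results, mirroring the practice of excluding compounds whose LD50
#' cannot be determined.
#'
#' @param residues residue tibble (see [validate_residues()] for the
#'   contract); at most one pollen and one nectar record per site, year, time
#'   point and compound.
#' @param tox toxicity reference tibble (see [read_toxicity_csv()]).
#' @param constants a [consumption_constants()] object.
#' @param registry a [rq_thresholds()] object used to set exceedance flags.
#' @param censoring_policy how non-detects enter the intake numerator:
#'   `"zero"` (default; non-detects contribute nothing) or `"half_lod"`
#'   (below-LOD records are replaced by `lod/2`; requires a
#'   `lod_ug_per_kg` column in `residues`).
#' @param chronic_policy which chronic endpoint to use when a compound has
#'   both an LC50 and an LDD50: `"min"` (default, the smaller and therefore
#'   more conservative), `"lc50"` or `"ldd50"`.
#' @return A tibble with one row per RQ: `site_id`, `proximity`, `year`,
#'   `time_point`, `compound`, `kind` (acute/chronic), `rq`, `endpoint_used`,
#'   `exceeds_acute_field`, `exceeds_acute_cage`, `exceeds_chronic`. The
#'   attribute `"skipped"` lists detected compounds lacking a usable acute
#'   endpoint.
#' @export
compute_site_rqs <- function(residues, tox,
                             constants = consumption_constants(),
                             registry = rq_thresholds(),
                             censoring_policy = c("zero", "half_lod"),
                             chronic_policy = c("min", "lc50", "ldd50")) {
  censoring_policy <- match.arg(censoring_policy)
  chronic_policy <- match.arg(chronic_policy)
  residues <- validate_residues(residues)
  tox <- validate_toxicity_reference(tox)

  dup <- residues |>
    dplyr::count(.data$site_id, .data$year, .data$time_point,
                 .data$compound, .data$matrix) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_validation(sprintf(
      "duplicate %s record(s) for site %s, compound %s",
      dup$matrix[1], dup$site_id[1], dup$compound[1]))
  }

  conc <- residues$concentration_ug_per_kg
  if (censoring_policy == "half_lod") {
    if (!"lod_ug_per_kg" %in% names(residues)) {
      abort_validation("censoring_policy 'half_lod' needs a lod_ug_per_kg column")
    }
    idx <- residues$censoring == "below_lod"
    conc[idx] <- residues$lod_ug_per_kg[idx] / 2
  }
  residues$.conc <- conc
  residues$.detected <- residues$censoring != "below_lod"

  wide <- residues |>
    dplyr::group_by(.data$site_id, .data$proximity, .data$year,
                    .data$time_point, .data$compound) |>
    dplyr::summarise(
      nectar = sum(.data$.conc[.data$matrix == "nectar"], 0),
      pollen = sum(.data$.conc[.data$matrix == "pollen"], 0),
      any_detection = any(.data$.detected),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$any_detection)

  if (nrow(wide) == 0) {
    return(empty_rq_results(skipped = character(0)))
  }

  tox_idx <- match(wide$compound, tox$compound)
  ld50 <- tox$acute_oral_ld50_ug_per_bee[tox_idx]
  skipped <- sort(unique(wide$compound[is.na(tox_idx) | is.na(ld50)]))
  keep <- !is.na(tox_idx) & !is.na(ld50)
  wide <- wide[keep, ]
  ld50 <- ld50[keep]
  tox_idx <- tox_idx[keep]

  acute <- tibble::tibble(
    site_id = wide$site_id, proximity = wide$proximity, year = wide$year,
    time_point = wide$time_point, compound = wide$compound,
    kind = "acute",
    rq = compute_rq_acute(wide$nectar, wide$pollen, ld50, constants),
    endpoint_used = "ld50"
  )

  chr <- chronic_endpoint(tox[tox_idx, ], policy = chronic_policy)
  has_chronic <- !is.na(chr$value)
  chronic <- tibble::tibble(
    site_id = wide$site_id[has_chronic],
    proximity = wide$proximity[has_chronic],
    year = wide$year[has_chronic],
    time_point = wide$time_point[has_chronic],
    compound = wide$compound[has_chronic],
    kind = "chronic",
    rq = compute_rq_chronic(wide$nectar[has_chronic],
                            wide$pollen[has_chronic],
                            chr$value[has_chronic], constants),
    endpoint_used = chr$used[has_chronic]
  )

  out <- dplyr::bind_rows(acute, chronic) |>
    dplyr::arrange(.data$site_id, .data$year, .data$time_point,
                   .data$compound, .data$kind)
  out <- flag_exceedances(out, registry)
  attr(out, "skipped") <- skipped
  out
}

flag_exceedances <- function(results, registry) {
  results$exceeds_acute_field <- results$kind == "acute" &
    results$rq > registry$acute_field
  results$exceeds_acute_cage <- results$kind == "acute" &
    results$rq > registry$acute_cage
  results$exceeds_chronic <- results$kind == "chronic" &
    results$rq > registry$chronic
  results
}

empty_rq_results <- function(skipped) {
  out <- tibble::tibble(
    site_id = character(0), proximity = character(0), year = character(0),
    time_point = character(0), compound = character(0), kind = character(0),
    rq = numeric(0), endpoint_used = character(0),
    exceeds_acute_field = logical(0), exceeds_acute_cage = logical(0),
    exceeds_chronic = logical(0)
  )
  attr(out, "skipped") <- skipped
  out
}

#' Total (additive) risk quotient per site and time point
#'
#' Sums the per-compound RQs of one kind over compounds within each (site,
#' year, time point), treating effects as additive. Groups with no results
#' are absent from the output rather than reported as zero.
#'
#' @param results RQ results from [compute_site_rqs()].
#' @param kind `"acute"` or `"chronic"`; all rows in `results` must be of
#'   this kind (filter first when mixing).
#' @return A tibble with `site_id`, `proximity`, `year`, `time_point`,
#'   `total_rq`, `n_compounds`.
#' @export
total_rq <- function(results, kind = c("acute", "chronic")) {
  kind <- match.arg(kind)
  if (nrow(results) > 0 && !all(results$kind == kind)) {
    abort_validation(sprintf(
      "total_rq of kind '%s' was given results of mixed kind; filter first",
      kind))
  }
  results |>
    dplyr::arrange(.data$site_id, .data$year, .data$time_point,
                   .data$compound) |>
    dplyr::group_by(.data$site_id, .data$proximity, .data$year,
                    .data$time_point) |>
    dplyr::summarise(total_rq = sum(.data$rq),
                     n_compounds = dplyr::n(), .groups = "drop")
}

#' Threshold exceedance report
#'
#' Counts, per compound and RQ kind, the number of distinct sites whose RQ
#' strictly exceeds each regulatory threshold at any year or time point.
#' Acute RQs are compared against the cage (0.4) and field (0.2) levels of
#' concern; chronic RQs against the chronic level (0.03). Quotients exactly
#' equal to a threshold are counted as non-exceedances.
#'
#' @inheritParams total_rq
#' @param registry a [rq_thresholds()] object.
#' @return A tibble with one row per compound x kind: `compound`, `kind`,
#'   `n_sites_exceed_acute_cage`, `n_sites_exceed_acute_field`,
#'   `n_sites_exceed_chronic` (NA for the kinds a row does not cover).
#' @export
exceedance_report <- function(results, registry = rq_thresholds()) {
  if (nrow(results) == 0) {
    return(tibble::tibble(compound = character(0), kind = character(0),
                          n_sites_exceed_acute_cage = integer(0),
                          n_sites_exceed_acute_field = integer(0),
                          n_sites_exceed_chronic = integer(0)))
  }
  results <- flag_exceedances(results, registry)  # idempotent re-derivation
  results |>
    dplyr::group_by(.data$compound, .data$kind) |>
    dplyr::summarise(
      n_sites_exceed_acute_cage = if (.data$kind[1] == "acute")
        dplyr::n_distinct(.data$site_id[.data$exceeds_acute_cage]) else NA_integer_,
      n_sites_exceed_acute_field = if (.data$kind[1] == "acute")
        dplyr::n_distinct(.data$site_id[.data$exceeds_acute_field]) else NA_integer_,
      n_sites_exceed_chronic = if (.data$kind[1] == "chronic")
        dplyr::n_distinct(.data$site_id[.data$exceeds_chronic]) else NA_integer_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$compound, .data$kind)
}

#' Flag sites for profit-scenario evaluation
#'
#' The bridge from exposure to economics: a site is flagged when any chronic
#' RQ there strictly exceeds the chronic level of concern, the condition
#' under which some colony mortality and sublethal effects on survivors are
#' assumed. The mapping from a flagged site to a specific health value h is
#' deliberately left to the user.
#'
#' @param results RQ results from [compute_site_rqs()].
#' @param chronic_threshold the chronic level of concern (default 0.03).
#' @return Character vector of flagged `site_id`s, sorted.
#' @export
flag_sites_for_scenarios <- function(results, chronic_threshold = 0.03) {
  sort(unique(results$site_id[results$kind == "chronic" &
                                results$rq > chronic_threshold]))
}
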