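test_that("acute and chronic RQ formulas match hand arithmetic", {
  expect_equal(compute_rq_acute(0, 0, ld50 = 0.5), 0)
  expect_equal(compute_rq_acute(1000, 0, ld50 = 0.14), 1.0)
  expect_equal(compute_rq_acute(50, 100, ld50 = 0.5),
               (50 * 140e-6 + 100 * 9.6e-6) / 0.5)  # 0.01592
  expect_equal(compute_rq_acute(50, 100, ld50 = 0.5), 0.01592)
  expect_equal(compute_rq_chronic(0, 0, chronic_endpoint = 0.01), 0)
  expect_equal(compute_rq_chronic(10, 10, chronic_endpoint = 0.01496), 0.1)
})

test_that("RQ is degree-1 homogeneous in residues and antitone in the endpoint", {
  set.seed(202)
  for (i in 1:25) {
    nectar <- runif(1, 0, 100); pollen <- runif(1, 0, 100)
    ld50 <- runif(1, 0.001, 10); c_scale <- runif(1, 0.1, 50)
    expect_equal(compute_rq_acute(c_scale * nectar, c_scale * pollen, ld50),
                 c_scale * compute_rq_acute(nectar, pollen, ld50))
    expect_lt(compute_rq_acute(nectar + 1, pollen, 2 * ld50),
              compute_rq_acute(nectar + 1, pollen, ld50))
    expect_equal(compute_rq_chronic(2 * nectar, 2 * pollen, ld50),
                 2 * compute_rq_chronic(nectar, pollen, ld50))
  }
})

test_that("RQ inputs are validated and missing endpoints name the compound", {
  expect_error(compute_rq_acute(-1, 0, ld50 = 0.5),
               class = "beecotox_validation_error")
  expect_error(compute_rq_acute(1, 0, ld50 = 0, compound = "dimethoate"),
               "dimethoate", class = "beecotox_toxicity_error")
  expect_error(compute_rq_chronic(1, 0, chronic_endpoint = NA_real_,
                                  compound = "linuron"),
               "linuron", class = "beecotox_toxicity_error")
})

test_that("site RQs handle missing matrices, non-detects and skipped compounds", {
  tox <- dplyr::bind_rows(
    tox_row("a", ld50 = 0.1),
    tox_row("b", ld50 = 0.2, ldd50 = 0.01),
    tox_row("c", lc50 = 0.05)  # no acute endpoint
  )
  residues <- dplyr::bind_rows(
    residue_row("s1", "nectar", "a", 10),                # nectar-only detection
    residue_row("s1", "pollen", "b", 5),
    residue_row("s1", "nectar", "b", 2),
    residue_row("s1", "nectar", "c", 4),                 # detected, no LD50
    residue_row("s2", "pollen", "a", 0)                  # all non-detect
  )
  out <- compute_site_rqs(residues, tox)
  # nectar-only: pollen contributes 0
  a1 <- out[out$compound == "a" & out$kind == "acute", ]
  expect_equal(nrow(a1), 1)
  expect_equal(a1$site_id, "s1")
  expect_equal(a1$rq, 10 * 140e-6 / 0.1)
  # compound b gets an acute and a chronic result
  expect_setequal(out$kind[out$compound == "b"], c("acute", "chronic"))
  b_chronic <- out[out$compound == "b" & out$kind == "chronic", ]
  expect_equal(b_chronic$rq, (2 * 140e-6 + 5 * 9.6e-6) / 0.01)
  expect_equal(b_chronic$endpoint_used, "ldd50")
  # compound c is skipped (reported), not an error; s2 all-non-detect absent
  expect_equal(attr(out, "skipped"), "c")
  expect_false("c" %in% out$compound)
  expect_false("s2" %in% out$site_id)
})

test_that("an all-non-detect table yields an empty result set", {
  residues <- dplyr::bind_rows(
    residue_row("s1", "nectar", "a", 0),
    residue_row("s1", "pollen", "a", 0)
  )
  out <- compute_site_rqs(residues, tox_row("a", ld50 = 1))
  expect_equal(nrow(out), 0)
})

test_that("duplicate matrix records are a data-integrity error", {
  residues <- dplyr::bind_rows(
    residue_row("s1", "nectar", "a", 1),
    residue_row("s1", "nectar", "a", 2)
  )
  expect_error(compute_site_rqs(residues, tox_row("a", ld50 = 1)),
               "duplicate", class = "beecotox_validation_error")
})

test_that("chronic endpoint selection uses the smaller value by default and is overridable", {
  tox <- tox_row("x", ld50 = 1, lc50 = 0.02, ldd50 = 0.01)
  residues <- dplyr::bind_rows(residue_row("s1", "nectar", "x", 10))
  intake <- 10 * 140e-6
  default_run <- compute_site_rqs(residues, tox)
  chr <- default_run[default_run$kind == "chronic", ]
  expect_equal(chr$rq, intake / 0.01)
  expect_equal(chr$endpoint_used, "ldd50")
  lc_run <- compute_site_rqs(residues, tox, chronic_policy = "lc50")
  expect_equal(lc_run$rq[lc_run$kind == "chronic"], intake / 0.02)
})

test_that("half-LOD censoring policy imputes lod/2 for non-detects", {
  tox <- tox_row("x", ld50 = 0.001)
  residues <- dplyr::bind_rows(
    residue_row("s1", "nectar", "x", 5),
    residue_row("s1", "pollen", "x", 0)
  )
  residues$lod_ug_per_kg <- 0.4
  zero <- compute_site_rqs(residues, tox)
  half <- compute_site_rqs(residues, tox, censoring_policy = "half_lod")
  expect_equal(zero$rq[zero$kind == "acute"], 5 * 140e-6 / 0.001)
  expect_equal(half$rq[half$kind == "acute"],
               (5 * 140e-6 + 0.2 * 9.6e-6) / 0.001)
})

test_that("site RQs agree with the brute-force oracle on a synthetic table", {
  cfg <- synthetic_config(n_near_sites = 2, n_far_sites = 2,
                          time_points = "T2", years = 2021, seed = 17)
  residues <- generate_residues(cfg)  # 4 sites x 20 compounds x 2 matrices = 160 rows, <= 100 detected keys
  tox <- default_toxicity_reference()
  fast <- compute_site_rqs(residues, tox)
  slow <- brute_force_site_rqs(residues, tox)
  key <- function(d) paste(d$site_id, d$year, d$time_point, d$compound, d$kind)
  slow <- slow[order(key(slow)), ]
  fast_ord <- fast[order(key(fast)), ]
  expect_equal(nrow(fast_ord), nrow(slow))
  expect_equal(fast_ord$rq, slow$rq, tolerance = 1e-12)
})

test_that("total RQ sums per site and time point and rejects mixed kinds", {
  tox <- dplyr::bind_rows(tox_row("a", ld50 = 1), tox_row("b", ld50 = 1),
                          tox_row("c", ld50 = 1))
  residues <- dplyr::bind_rows(
    residue_row("s1", "nectar", "a", 0.01 / 140e-6),
    residue_row("s1", "nectar", "b", 0.02 / 140e-6),
    residue_row("s1", "nectar", "c", 0.03 / 140e-6),
    residue_row("s2", "nectar", "a", 0.05 / 140e-6)
  )
  out <- compute_site_rqs(residues, tox)
  totals <- total_rq(out, "acute")
  expect_equal(totals$total_rq[totals$site_id == "s1"], 0.06)
  expect_equal(totals$n_compounds[totals$site_id == "s1"], 3L)
  # singleton group: total equals the single RQ
  expect_equal(totals$total_rq[totals$site_id == "s2"], 0.05)
  # total >= max individual member
  expect_true(all(totals$total_rq + 1e-12 >=
                    tapply(out$rq, out$site_id, max)[totals$site_id]))
  # permuting input order leaves totals unchanged
  perm <- total_rq(out[sample(nrow(out)), ], "acute")
  expect_equal(dplyr::arrange(perm, site_id), dplyr::arrange(totals, site_id))
  expect_error(total_rq(out, "chronic"), "mixed",
               class = "beecotox_validation_error")
})

test_that("exceedance counting is strict and counts distinct sites", {
  tox <- tox_row("thiamethoxam", ld50 = 1, ldd50 = 0.01)
  intake_for <- function(rq) rq * 0.01 / 140e-6  # nectar conc giving chronic rq
  residues <- dplyr::bind_rows(
    residue_row("s1", "nectar", "thiamethoxam", intake_for(0.031)),
    residue_row("s2", "nectar", "thiamethoxam", intake_for(0.03)),   # boundary
    residue_row("s3", "nectar", "thiamethoxam", intake_for(0.029)),
    # same site exceeding twice still counts once
    residue_row("s1", "nectar", "thiamethoxam", intake_for(0.05),
                time_point = "T3")
  )
  out <- compute_site_rqs(residues, tox)
  rep <- exceedance_report(out)
  chronic <- rep[rep$kind == "chronic", ]
  expect_equal(chronic$n_sites_exceed_chronic, 1L)
  # boundary equality is a non-exceedance
  s2 <- out[out$site_id == "s2" & out$kind == "chronic", ]
  expect_equal(s2$rq, 0.03, tolerance = 1e-12)
  expect_false(s2$exceeds_chronic)
  # flags are idempotent under recomputation
  expect_identical(exceedance_report(out), rep)
  # all-zero RQs: no exceedances anywhere
  zero_rep <- exceedance_report(out[0, ])
  expect_equal(nrow(zero_rep), 0)
})

test_that("a planted exceedance pattern is counted exactly", {
  planted <- planted_exceedance_config(seed = 123)
  residues <- generate_residues(planted$config)
  out <- compute_site_rqs(residues, default_toxicity_reference())
  rep <- exceedance_report(out)
  thia <- rep[rep$compound == "thiamethoxam" & rep$kind == "chronic", ]
  clo <- rep[rep$compound == "clothianidin" & rep$kind == "chronic", ]
  expect_equal(thia$n_sites_exceed_chronic, length(planted$thia_sites))
  expect_equal(clo$n_sites_exceed_chronic, length(planted$clo_sites))
  expect_setequal(flag_sites_for_scenarios(out),
                  union(planted$thia_sites, planted$clo_sites))
})
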