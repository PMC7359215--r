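test_that("compartment doses follow the bilinear S-value form", {
  s <- s_value_tc99m()
  # unit nuclear decay: doses are the first S-matrix column
  d <- compartment_doses(cumulated_activity(1, 0), s)
  expect_equal(d$dose_nucleus_gy, 1.19e-2)
  expect_equal(d$dose_cytoplasm_gy, 1.82e-4)

  d0 <- compartment_doses(cumulated_activity(0, 0), s)
  expect_equal(d0$dose_nucleus_gy, 0)
  expect_equal(d0$dose_cell_gy, 0)
  expect_true(is.na(d0$nuclear_dose_fraction))

  # hand bilinear expansion for 100 Bq.s in each compartment
  d100 <- compartment_doses(cumulated_activity(100, 100), s)
  expect_equal(d100$dose_nucleus_gy, 1.2082, tolerance = 1e-12)
  expect_equal(d100$dose_cytoplasm_gy, 1.9220e-1, tolerance = 1e-12)
  expect_equal(d100$dose_cell_gy, d100$dose_nucleus_gy + d100$dose_cytoplasm_gy)
})

test_that("mass-weighted total-dose convention averages by compartment mass", {
  s <- s_value_tc99m()
  ph <- cell_phantom()
  act <- cumulated_activity(50, 150)
  d_sum <- compartment_doses(act, s)
  d_mw <- compartment_doses(act, s, total = "mass_weighted", phantom = ph)
  m <- region_masses(ph)
  expect_equal(d_mw$dose_cell_gy,
               (d_sum$dose_nucleus_gy * m$nucleus_kg +
                d_sum$dose_cytoplasm_gy * m$cytoplasm_kg) /
                 (m$nucleus_kg + m$cytoplasm_kg))
  expect_lt(d_mw$dose_cell_gy, d_sum$dose_cell_gy)
  expect_error(compartment_doses(act, s, total = "mass_weighted"), "phantom")
})

test_that("nuclear dose share reproduces the published mean-uptake anchors", {
  s <- s_value_tc99m()
  expect_equal(nuclear_dose_fraction_from_uptake(0.45, s), 0.84, tolerance = 0.01 / 0.84)
  expect_equal(nuclear_dose_fraction_from_uptake(0.22, s), 0.66, tolerance = 0.01 / 0.66)
  expect_true(nuclear_dose_fraction_from_uptake(0.45, s) > 0.83 &&
              nuclear_dose_fraction_from_uptake(0.45, s) < 0.86)
  expect_true(nuclear_dose_fraction_from_uptake(0.22, s) > 0.64 &&
              nuclear_dose_fraction_from_uptake(0.22, s) < 0.67)
  # all-nuclear limit: direct substitution of the matrix entries
  expect_equal(nuclear_dose_fraction_from_uptake(1, s),
               1.19e-2 / (1.19e-2 + 1.82e-4))
})

test_that("nuclear dose share is scale invariant and monotone in uptake", {
  s <- s_value_tc99m()
  f <- 0.37
  share_ref <- nuclear_dose_fraction_from_uptake(f, s)
  for (scale in c(1e-3, 1, 1e6)) {
    act <- cumulated_activity(scale * f, scale * (1 - f))
    expect_equal(compartment_doses(act, s)$nuclear_dose_fraction, share_ref,
                 tolerance = 1e-12)
  }
  ff <- seq(0, 1, by = 0.05)
  expect_true(all(diff(nuclear_dose_fraction_from_uptake(ff, s)) > 0))
})

test_that("the packaged 99mTc matrix is reciprocal and sanity-ordered", {
  s <- s_value_tc99m()
  expect_identical(s$s_n_cy, s$s_cy_n)
  expect_true(s$reciprocal)
  expect_true(s$s_n_n > s$s_cy_cy && s$s_cy_cy > s$s_n_cy)
  expect_warning(s_value_matrix(1e-4, 1e-4, 1e-4, 1e-3), "ordering")
  expect_error(s_value_matrix(0, 1, 1, 1), "positive")
})

test_that("S-value matrix JSON round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  write_s_value_json(s_value_tc99m(), path)
  s2 <- read_s_value_json(path)
  expect_equal(s2$s_n_n, 1.19e-2)
  expect_equal(s2$radionuclide, "Tc99m_MIRD")
})

test_that("dose_table chains kinetics and dosimetry row by row", {
  p <- decay_params()
  s <- s_value_tc99m()
  recs <- list(
    uptake_record(7.4e5, 2e4, nuclear_fraction = 0.4, compound = "C3"),
    uptake_record(1.85e5, 1e4, nuclear_fraction = 0.5, compound = "C3"))
  tab <- dose_table(recs, p, s, nuclear_fraction_mode = "per_record")
  expect_equal(nrow(tab), 2L)
  # sorted by applied activity
  expect_equal(tab$applied_activity_bq, c(1.85e5, 7.4e5))

  # oracle: independent 2x2 matrix product per record
  for (i in 1:2) {
    r <- recs[[if (tab$applied_activity_bq[i] == 7.4e5) 1 else 2]]
    atilde <- time_integrated_activity(
      back_extrapolate_a0(cpm_to_bq(r$internalized_cpm, 0.54), 24, p), 24, p)
    smat <- matrix(c(s$s_n_n, s$s_cy_n, s$s_n_cy, s$s_cy_cy), 2, 2)
    dvec <- smat %*% c(atilde * r$nuclear_fraction,
                       atilde * (1 - r$nuclear_fraction))
    expect_equal(tab$dose_nucleus_gy[i], dvec[1])
    expect_equal(tab$dose_cytoplasm_gy[i], dvec[2])
  }

  # linearity: doubling counts doubles doses
  recs2 <- lapply(recs, function(r) { r$internalized_cpm <- 2 * r$internalized_cpm; r })
  tab2 <- dose_table(recs2, p, s, nuclear_fraction_mode = "per_record")
  expect_equal(tab2$dose_cell_gy, 2 * tab$dose_cell_gy)

  # zero internalization gives a zero-dose row
  z <- dose_table(list(uptake_record(1e5, 0, surface_cpm = 1e4)), p, s)
  expect_equal(z$dose_cell_gy, 0)

  # empty input gives an empty table, not an error
  expect_equal(nrow(dose_table(list(), p, s)), 0L)
})

test_that("mean nuclear-fraction mode pools the fraction per compound", {
  p <- decay_params()
  s <- s_value_tc99m()
  recs <- list(
    uptake_record(1e5, 1e4, nuclear_fraction = 0.40, compound = "C3"),
    uptake_record(2e5, 1e4, nuclear_fraction = 0.50, compound = "C3"),
    uptake_record(1e5, 1e4, nuclear_fraction = 0.22, compound = "C5"))
  tab <- dose_table(recs, p, s, nuclear_fraction_mode = "mean")
  c3 <- tab[tab$compound == "C3", ]
  expect_equal(unique(c3$nuclear_dose_fraction),
               nuclear_dose_fraction_from_uptake(0.45, s))
  expect_equal(tab$nuclear_dose_fraction[tab$compound == "C5"],
               nuclear_dose_fraction_from_uptake(0.22, s))
})
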