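ph <- cell_phantom()
sm <- stopping_model()

test_that("emission points are uniform in the named volume", {
  set.seed(11)
  pts <- sample_emission_point("central_sphere", ph, 2e4)
  r <- sqrt(rowSums(pts^2))
  expect_true(all(r <= ph$r_source_um))
  # uniform-ball radius: E[(r/R)^3] = 1/2
  expect_equal(mean((r / ph$r_source_um)^3), 0.5, tolerance = 0.02)

  ptsn <- sample_emission_point("nucleus", ph, 2e4)
  rn <- sqrt(rowSums(ptsn^2))
  expect_true(all(rn <= ph$r_nucleus_um))
  expect_equal(mean((rn / ph$r_nucleus_um)^3), 0.5, tolerance = 0.02)

  ptsc <- sample_emission_point("cytoplasm_shell", ph, 5e3)
  rc <- sqrt(rowSums(ptsc^2))
  expect_true(all(rc >= ph$r_nucleus_um & rc <= ph$r_cell_um))

  expect_error(sample_emission_point("medium", ph, 1), "unknown source region")
})

test_that("low-energy electrons at the centre deposit entirely in the nucleus", {
  d <- csda_deposit(c(0, 0, 0), c(0, 0, 1), 0.05, ph, sm)
  expect_equal(d$nucleus, 0.05)
  expect_equal(d$cytoplasm, 0)
  expect_equal(d$escaped, 0)
})

test_that("energy is conserved exactly for every history", {
  set.seed(7)
  for (e in c(0.02, 0.5, 2, 15, 120)) {
    start <- sample_emission_point("cytoplasm_shell", ph, 50)
    dir <- sample_direction(50)
    for (i in 1:50) {
      d <- csda_deposit(start[i, ], dir[i, ], e, ph, sm)
      expect_equal(d$nucleus + d$cytoplasm + d$escaped, e, tolerance = 1e-9)
    }
  }
})

test_that("boundary-bridging deposits match an independent energy-loss integration", {
  # start 1 um from the nucleus boundary heading outward along +x:
  # 1 um of nucleus, then 2 um of cytoplasm, then escape.
  e0 <- 10    # range about 2.5 um: stops inside the cytoplasm
  # independent oracle: RK4 on dE/ds = -S(E), never using the range tables
  rk4_energy <- function(e, s_len, n = 20000) {
    h <- s_len / n
    for (i in seq_len(n)) {
      if (e <= sm$e_floor_keV) return(0)
      k1 <- -sm$stopping(e)
      k2 <- -sm$stopping(max(e + h / 2 * k1, sm$e_floor_keV))
      k3 <- -sm$stopping(max(e + h / 2 * k2, sm$e_floor_keV))
      k4 <- -sm$stopping(max(e + h * k3, sm$e_floor_keV))
      e <- e + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    e
  }
  e_at_boundary <- rk4_energy(e0, 1)
  d <- csda_deposit(c(1, 0, 0), c(1, 0, 0), e0, ph, sm)
  expect_equal(d$nucleus, e0 - e_at_boundary, tolerance = 2e-3)
  expect_equal(d$cytoplasm, e_at_boundary, tolerance = 2e-3)
  expect_equal(d$escaped, 0)

  # higher energy: crosses the cell boundary with energy to spare
  e1 <- 40    # range about 26 um
  eb <- rk4_energy(e1, 1)
  ec <- rk4_energy(e1, 3)
  d1 <- csda_deposit(c(1, 0, 0), c(1, 0, 0), e1, ph, sm)
  expect_equal(d1$nucleus, e1 - eb, tolerance = 2e-3)
  expect_equal(d1$cytoplasm, eb - ec, tolerance = 2e-3)
  expect_equal(d1$escaped, ec, tolerance = 2e-3)
})

test_that("a fully absorbed single line gives S(N<-source) = E/m_N exactly", {
  sp <- electron_spectrum(0.1, 1)
  res <- run_s_value_mc(sp, ph, n_histories = 500, seed = 3)
  m <- region_masses(ph)
  expect_equal(res$s_nucleus_gy_per_bqs,
               0.1 * 1.602176634e-16 / m$nucleus_kg, tolerance = 1e-12)
  expect_equal(res$edep_cytoplasm_keV_per_decay, 0)
  expect_equal(nuclear_dose_share_mc(res), 1.0)

  # near-exact for a homogeneous nucleus source too: only emissions within
  # one 5 nm range of the boundary can leak a sliver of energy
  resn <- run_s_value_mc(sp, ph, source_region = "nucleus",
                         n_histories = 500, seed = 3)
  expect_equal(resn$s_nucleus_gy_per_bqs,
               0.1 * 1.602176634e-16 / m$nucleus_kg, tolerance = 2e-3)
})

test_that("S estimates are linear in the yields", {
  sp1 <- toy_spectrum("tc99m_like")
  sp2 <- electron_spectrum(sp1$energy_keV, 2 * sp1$yield_per_decay)
  r1 <- run_s_value_mc(sp1, ph, n_histories = 2000, seed = 5)
  r2 <- run_s_value_mc(sp2, ph, n_histories = 2000, seed = 5)
  expect_equal(r2$s_nucleus_gy_per_bqs, 2 * r1$s_nucleus_gy_per_bqs)
  expect_equal(r2$s_cytoplasm_gy_per_bqs, 2 * r1$s_cytoplasm_gy_per_bqs)
  expect_equal(r2$edep_escaped_keV_per_decay, 2 * r1$edep_escaped_keV_per_decay)
})

test_that("identical seeds give identical transport results", {
  sp <- toy_spectrum("tc99m_like")
  r1 <- run_s_value_mc(sp, ph, n_histories = 3000, seed = 99)
  r2 <- run_s_value_mc(sp, ph, n_histories = 3000, seed = 99)
  expect_identical(r1$edep_nucleus_keV_per_decay, r2$edep_nucleus_keV_per_decay)
  expect_identical(r1$s_cytoplasm_gy_per_bqs, r2$s_cytoplasm_gy_per_bqs)
  r3 <- run_s_value_mc(sp, ph, n_histories = 3000, seed = 100)
  expect_false(identical(r1$edep_nucleus_keV_per_decay,
                         r3$edep_nucleus_keV_per_decay))
})

test_that("standard errors shrink as 1/sqrt(n) over a history ladder", {
  sp <- electron_spectrum(120, 1)   # high-energy line: real per-history variance
  ns <- c(2000, 8000, 32000)
  ses <- vapply(ns, function(n) {
    run_s_value_mc(sp, ph, n_histories = n, seed = 21)$edep_nucleus_se
  }, numeric(1))
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.15)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.15)
})

test_that("cytoplasm deposit vanishes as the nucleus fills the cell", {
  sp <- toy_spectrum("tc99m_like")
  ph_thin <- cell_phantom(r_source_um = 0.7, r_nucleus_um = 3.999, r_cell_um = 4)
  res <- run_s_value_mc(sp, ph_thin, n_histories = 2000, seed = 13)
  full <- run_s_value_mc(sp, ph, n_histories = 2000, seed = 13)
  expect_lt(res$edep_cytoplasm_keV_per_decay,
            0.05 * full$edep_cytoplasm_keV_per_decay + 1e-6)
})

test_that("aggregate energy bookkeeping balances emitted energy", {
  sp <- toy_spectrum("tc99m_like")
  res <- run_s_value_mc(sp, ph, n_histories = 5000, seed = 17)
  expect_equal(res$edep_nucleus_keV_per_decay + res$edep_cytoplasm_keV_per_decay +
                 res$edep_escaped_keV_per_decay,
               spectrum_energy_per_decay(sp), tolerance = 1e-9)
})

test_that("nuclear dose share handles the degenerate and symmetric cases", {
  res <- run_s_value_mc(electron_spectrum(0.1, 1), ph, n_histories = 100, seed = 1)
  expect_equal(nuclear_dose_share_mc(res), 1.0)
  # equal doses in both regions: share is 1/2 by definition
  fake <- res
  m <- region_masses(ph)
  fake$edep_nucleus_keV_per_decay <- 1 * m$nucleus_kg
  fake$edep_cytoplasm_keV_per_decay <- 1 * m$cytoplasm_kg
  expect_equal(nuclear_dose_share_mc(fake), 0.5)
})

test_that("spectrum files round-trip and malformed lines are reported", {
  sp <- toy_spectrum("tc99m_like")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  sp2 <- read_spectrum(path)
  expect_equal(sp2$energy_keV, sp$energy_keV)
  expect_equal(sp2$yield_per_decay, sp$yield_per_decay)

  writeLines(c("# comment", "1.0 0.5", "oops"), path)
  expect_error(read_spectrum(path), "line 3")
  expect_error(run_s_value_mc(electron_spectrum(1, 1)[0, ], ph, seed = 1),
               "empty|spectrum")
})

test_that("the packaged fixture spectrum file matches the in-code fixture", {
  path <- system.file("extdata", "tc99m_like_synthetic_spectrum.tsv",
                      package = "celldose")
  sp_file <- read_spectrum(path)
  sp_code <- toy_spectrum("tc99m_like")
  expect_equal(sp_file$energy_keV, sp_code$energy_keV)
  expect_equal(sp_file$yield_per_decay, sp_code$yield_per_decay)
})

test_that("the power-law range fallback transports without the table", {
  m2 <- range_energy_model()
  d <- csda_deposit(c(0, 0, 0), c(1, 0, 0), 10, ph, m2)
  expect_equal(d$nucleus + d$cytoplasm + d$escaped, 10, tolerance = 1e-9)
  expect_equal(m2$range(10), 0.0431 * 10^1.77, tolerance = 0.01)
})
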