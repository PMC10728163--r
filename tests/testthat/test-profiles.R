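test_that("capillarity profile of the model pore reproduces the closed form", {
  geo <- pore_geometry(1.04, 2.8, 104)
  liq <- liquid_params()
  prof <- build_cnt_profile(geo, liq)
  st <- locate_states(prof)
  # hand evaluation: wall term 2 pi R L gamma |cos theta| = 36.2 kBT,
  # meniscus c_m gamma pi R^2 = 13.9 kBT, dry favoured by the difference
  kbt <- 1.380649e-23 * 310
  wall <- 2 * pi * 0.52e-9 * 2.8e-9 * 0.070 * abs(cos(104 * pi / 180)) / kbt
  menisc <- 0.070 * pi * (0.52e-9)^2 / kbt
  expect_equal(st$gap, wall - menisc, tolerance = 1e-10) # minima at exact endpoints
  # barriers carry one grid step of the ramp (saddle sits one step inside)
  expect_equal(st$barrier_wetting, wall, tolerance = 0.01)
  expect_equal(st$barrier_drying, menisc, tolerance = 0.02)
  expect_identical(st$global_state, "dry")
  expect_equal(st$xi_dry, 0)
  expect_equal(st$xi_wet, 1)
})

test_that("neutral wall (theta = 90) leaves a single wet state costing the meniscus term", {
  geo <- pore_geometry(1.04, 2.8, 90)
  prof <- build_cnt_profile(geo, liquid_params())
  # wall term vanishes; all dry states cost +meniscus, wet is global minimum
  expect_gt(min(prof$free_energy[prof$xi < 1]), 0)
  expect_equal(prof$free_energy[prof$xi == 1], 0)
  err <- tryCatch(locate_states(prof), hymn_single_state = function(e) e)
  expect_s3_class(err, "hymn_single_state")
  expect_equal(err$xi_min, 1)
})

test_that("dry state is favoured iff aspect ratio exceeds c_m/(4|cos theta|)", {
  liq <- liquid_params()
  for (theta in c(100, 104, 110)) {
    ar_crit <- 1 / (4 * abs(cos(theta * pi / 180)))
    for (ar in c(0.8, 0.97, 1.03, 1.3) * ar_crit) {
      d <- 1.0
      prof <- build_cnt_profile(pore_geometry(d, ar * d, theta), liq)
      # brute-force sign evaluation of W at the two end states
      w_dry <- prof$free_energy[1]
      w_wet <- prof$free_energy[nrow(prof)]
      expect_identical(w_dry < w_wet, ar > ar_crit)
    }
  }
})

test_that("electrowetting tilt is linear in xi, quadratic-plus-dipole in V", {
  prof <- make_double_well()
  ew <- electrowetting(a_ew = 12.037, mu_ew = 0)
  expect_equal(apply_voltage(prof, ew, 0)$free_energy, prof$free_energy)
  tilted <- apply_voltage(prof, ew, 1.2)
  expect_equal(tilted$free_energy[1], prof$free_energy[1]) # F(0) preserved
  expect_equal(
    tilted$free_energy[nrow(tilted)] - prof$free_energy[nrow(prof)],
    -12.037 * 1.2^2
  )
  # mu = 0: symmetric under V -> -V
  expect_equal(
    apply_voltage(prof, ew, -1.2)$free_energy,
    tilted$free_energy
  )
  # dipole term breaks the symmetry
  ewb <- electrowetting(a_ew = 12.037, mu_ew = 5)
  expect_false(isTRUE(all.equal(
    apply_voltage(prof, ewb, 0.5)$free_energy,
    apply_voltage(prof, ewb, -0.5)$free_energy
  )))
  # with a_ew solving gap = a V^2 (xi_wet - xi_dry), the original minima
  # positions become degenerate at 1.2 V
  a_cf <- 13 / (1.2^2 * (0.90 - 0.15))
  tl <- apply_voltage(prof, electrowetting(a_ew = a_cf), 1.2)
  i_dry <- which.min(abs(tl$xi - 0.15))
  i_wet <- which.min(abs(tl$xi - 0.90))
  expect_equal(tl$free_energy[i_wet], tl$free_energy[i_dry], tolerance = 1e-9)
})

test_that("locate_states round-trips the generator and flags degenerate profiles", {
  st <- locate_states(make_double_well(B_w = 18, B_d = 5))
  expect_equal(st$barrier_wetting, 18)
  expect_equal(st$barrier_drying, 5)
  expect_equal(st$gap, 13)
  expect_identical(st$global_state, "dry")
  sym <- locate_states(make_double_well(B_w = 10, B_d = 10))
  expect_equal(sym$gap, 0)
  expect_equal(sym$barrier_wetting, sym$barrier_drying)
  mono <- filling_profile(seq(0, 1, length.out = 51), seq(0, 5, length.out = 51))
  expect_error(locate_states(mono), class = "hymn_single_state")
})

test_that("critical voltage matches the calibrated anchor and its edge cases", {
  prof <- make_double_well()
  ew <- calibrate_coupling(prof, target_vc = 1.2)
  expect_equal(critical_voltage(prof, ew, v_max = 3, tol = 1e-3), 1.2,
    tolerance = 2e-3
  )
  # closed-form inversion of gap = a V^2 (xi_wet - xi_dry) gives ~12.04; the
  # tabulated-profile calibration relocates the minima and lands within 1%
  expect_equal(ew$a_ew, 13 / (1.2^2 * 0.75), tolerance = 0.01)
  expect_equal(ew$v_c_reference, 1.2)
  # wet already global at 0 V
  wet_prof <- make_double_well(B_w = 5, B_d = 18)
  expect_equal(critical_voltage(wet_prof, ew, v_max = 3), 0)
  # no coupling, no switching
  expect_error(
    critical_voltage(prof, electrowetting(a_ew = 0), v_max = 3),
    class = "hymn_no_switch"
  )
})

test_that("critical voltage is monotone non-increasing in the coupling strength", {
  prof <- make_double_well()
  vcs <- vapply(
    c(8, 10, 12.1, 15, 20),
    function(a) critical_voltage(prof, electrowetting(a_ew = a), v_max = 5),
    numeric(1)
  )
  expect_true(all(diff(vcs) <= 1e-9))
})

test_that("coupling calibration scales linearly with the gap and handles gap 0", {
  a1 <- calibrate_coupling(make_double_well(B_w = 18, B_d = 5), 1.2)$a_ew
  a2 <- calibrate_coupling(make_double_well(B_w = 31, B_d = 5), 1.2)$a_ew # gap 26
  expect_equal(a2 / a1, 2, tolerance = 0.05)
  a0 <- calibrate_coupling(make_double_well(B_w = 10, B_d = 10), 1.2)
  expect_equal(a0$a_ew, 0)
  expect_error(calibrate_coupling(make_double_well(B_w = 5, B_d = 18), 1.2))
})

test_that("profile TSV round-trips with comments and blank lines tolerated", {
  prof <- apply_voltage(make_double_well(), electrowetting(a_ew = 2), 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, path)
  lines <- readLines(path)
  writeLines(c(lines[1], "", "# extra comment", lines[-1]), path)
  back <- read_profile_tsv(path)
  expect_equal(back$xi, prof$xi)
  expect_equal(back$free_energy, prof$free_energy)
  expect_equal(attr(back, "voltage"), 0.5)
})
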