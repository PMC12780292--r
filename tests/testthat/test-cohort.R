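# Mode bank and synthetic cohort generator.

test_that("mode bank is orthonormal in the declared order", {
  mb <- coarse_modes()
  M <- sapply(mb, function(m) m$displacement)
  G <- crossprod(M)
  expect_lt(max(abs(G - diag(4))), 1e-10)
  expect_identical(names(mb), c("size", "motion", "sphericity", "contraction"))
})

test_that("mode directions move the metrics they should", {
  tmpl <- coarse_template()
  mb <- coarse_modes()
  v0 <- concat_vector(tmpl)
  lab <- tmpl$labels$surfaces
  bump <- function(mode, mult = 2) {
    unconcat_vector(v0 + mult * sqrt(mode$variance) * mode$displacement, tmpl)
  }
  # +2 SD size raises LVEDV and LV mass
  big <- bump(mb$size)
  expect_gt(surface_volume(big$ed, lab$lv_endo),
            surface_volume(tmpl$ed, lab$lv_endo))
  expect_gt(lv_mass(big), lv_mass(tmpl))
  # +2 SD motion raises MAPSE and TAPSE; GCS responds only weakly (the
  # annular-tilt component perturbs ring lengths at second order)
  mov <- bump(mb$motion)
  d_mapse <- valve_excursion(mov, "mitral") - valve_excursion(tmpl, "mitral")
  expect_gt(d_mapse, 1)
  expect_gt(valve_excursion(mov, "tricuspid"),
            valve_excursion(tmpl, "tricuspid"))
  expect_lt(abs(gcs_mid(mov, "lv") / gcs_mid(tmpl, "lv") - 1), 0.2)
  # +2 SD contraction raises LVEF and GCS
  con <- bump(mb$contraction)
  ef <- function(s) {
    edv <- surface_volume(s$ed, lab$lv_endo)
    100 * (edv - surface_volume(s$es, lab$lv_endo)) / edv
  }
  expect_gt(ef(con), ef(tmpl))
  expect_gt(gcs_mid(con, "lv"), gcs_mid(tmpl, "lv"))
})

test_that("simulation is deterministic and reproduces planted variance", {
  tmpl <- coarse_template()
  mb <- coarse_modes()
  spec <- cohort_spec(n_reference = 30, n_disease = integer(), seed = 99,
                      noise_sd = 0.3)
  a <- simulate_cohort(tmpl, mb, spec)
  b <- simulate_cohort(tmpl, mb, spec)
  expect_identical(a$records, b$records)
  expect_identical(a$shapes[[7]]$ed$vertices, b$shapes[[7]]$ed$vertices)

  # planted score variance: law-of-large-numbers check at n = 100,
  # median over several seeds (a single draw has ~14% sampling SD)
  v_size <- v_con <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_cohort(tmpl, mb,
                           cohort_spec(n_reference = 100,
                                       n_disease = integer(),
                                       seed = s, noise_sd = 0))
    v_size[s] <- stats::var(sim$records$score_size)
    v_con[s] <- stats::var(sim$records$score_contraction)
  }
  expect_equal(stats::median(v_size), mb$size$variance, tolerance = 0.30)
  expect_equal(stats::median(v_con), mb$contraction$variance,
               tolerance = 0.30)
})

test_that("participant records are physiologic and consistent", {
  sim <- coarse_cohort(n = 60)
  r <- sim$records
  expect_true(all(r$height > 0 & r$weight > 0 & r$sbp_raw > 0))
  expect_equal(r$bmi, r$weight / (r$height / 100)^2, tolerance = 1e-9)
  expect_true(all(r$group == "Reference"))
  expect_true(all(grepl("^S\\d+$", r$id)))
})

test_that("SBP medication adjustment and BSA follow their definitions", {
  expect_equal(adjust_sbp(120, TRUE), 135)
  expect_equal(adjust_sbp(120, FALSE), 120)
  expect_equal(adjust_sbp(c(100, 110), c(TRUE, FALSE)), c(115, 110))

  expect_equal(body_surface_area(180, 80),
               0.007184 * 180^0.725 * 80^0.425, tolerance = 1e-12)
  expect_equal(body_surface_area(180, 80), 1.9966, tolerance = 1e-4)
  expect_equal(body_surface_area(169, 75), 1.85, tolerance = 0.01)
  # power law in weight
  expect_equal(body_surface_area(170, 140) / body_surface_area(170, 70),
               2^0.425, tolerance = 1e-12)
  expect_error(body_surface_area(-1, 70), "positive")
})

test_that("calibrated reference cohort approximates published normals", {
  sim <- fixture("calib_cohort", function() {
    simulate_cohort(default_template(),
                    fixture("default_modes",
                            function() build_mode_bank(default_template())),
                    cohort_spec(n_reference = 120, n_disease = integer(),
                                seed = 17))
  })
  mt <- compute_metric_table(sim$shapes, sim$records)
  expect_equal(mean(mt$LVM), 123, tolerance = 0.10)
  expect_equal(mean(mt$LVEDV), 146, tolerance = 0.15)
  expect_equal(mean(mt$LVEF), 54.2, tolerance = 0.15)
  expect_equal(mean(mt$LV_GCS_mid), 27.0, tolerance = 0.15)
  expect_equal(mean(mt$MAPSE), 12.2, tolerance = 0.15)
  expect_equal(mean(adjust_sbp(sim$records$sbp_raw,
                               sim$records$bp_medication)),
               138, tolerance = 0.10)
})
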