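# Functional metrics: strain, excursion, afterload, metric table.

test_that("geometric strain follows its definition", {
  expect_equal(geometric_strain(100, 80), 20)
  expect_equal(geometric_strain(100, 100), 0)
  expect_error(geometric_strain(0, 10), "positive")
})

test_that("uniform ES scaling gives identical strain on every ring and line", {
  tmpl <- coarse_template()
  shrunk <- tmpl
  ctr <- colMeans(tmpl$ed$vertices)
  shrunk$es <- new_mesh(sweep(sweep(tmpl$ed$vertices, 2, ctr) * 0.85,
                              2, ctr, `+`),
                        tmpl$ed$faces, validate = FALSE)
  for (s in c("lv_endo", "rv_endo")) {
    for (r in shrunk$labels$rings[[s]][c(1, 4, 8)]) {
      expect_equal(geometric_strain(ring_arc_length(shrunk$ed, r),
                                    ring_arc_length(shrunk$es, r)),
                   15, tolerance = 1e-9)
    }
  }
  expect_equal(gls(shrunk, "lv"), 15, tolerance = 1e-9)
  expect_equal(gls(shrunk, "rv"), 15, tolerance = 1e-9)
  expect_equal(gcs_mid(shrunk, "lv"), 15, tolerance = 1e-9)
})

test_that("rigid ring translation yields zero circumferential strain", {
  tmpl <- coarse_template()
  slid <- tmpl
  slid$es <- new_mesh(sweep(tmpl$ed$vertices, 2, c(0, 0, -10), `+`),
                      tmpl$ed$faces, validate = FALSE)
  expect_equal(gcs_mid(slid, "lv"), 0, tolerance = 1e-12)
  expect_equal(gcs_mid(slid, "rv"), 0, tolerance = 1e-12)
  # and a pure 10 mm translation is exactly a 10 mm excursion
  expect_equal(valve_excursion(slid, "mitral"), 10, tolerance = 1e-12)
  expect_equal(valve_excursion(slid, "tricuspid"), 10, tolerance = 1e-12)
})

test_that("per-line and pooled GLS differ only for unequal line lengths", {
  # two-line toy: equal lengths -> identical; unequal -> different
  v <- rbind(c(0, 0, 0), c(0, 0, 10), c(1, 0, 0), c(1, 0, 10),
             c(2, 0, 0), c(2, 0, 20))
  mk <- function(es_scale) {
    es <- v
    es[, 3] <- v[, 3] * es_scale
    labels <- new_labels(
      surfaces = list(lv_endo = 1:6, lv_epi = 7L, rv_endo = 8L, rv_epi = 9L),
      valves = list(mitral = 1:3, tricuspid = 1:3, aortic = 1:3),
      apex = 1L, rings = list(),
      long_lines = list(lv_endo = list(c(1L, 2L), c(5L, 6L))))
    f <- rbind(c(1L, 2L, 3L))
    structure(list(id = "toy",
                   ed = new_mesh(rbind(v, c(9, 9, 9), c(8, 8, 8), c(7, 7, 7)),
                                 f, validate = FALSE),
                   es = new_mesh(rbind(es, c(9, 9, 9), c(8, 8, 8), c(7, 7, 7)),
                                 f, validate = FALSE),
                   labels = labels), class = "biv_shape")
  }
  toy <- mk(0.8)
  expect_equal(gls(toy, "lv"), 20)          # both lines shorten 20%
  expect_equal(gls(toy, "lv", pooled = TRUE), 20)
  # now shorten only the long line
  toy2 <- mk(1)
  toy2$es$vertices[6, 3] <- 10              # line 2: 20 -> 10 mm (50%)
  expect_equal(gls(toy2, "lv"), mean(c(0, 50)))
  expect_equal(gls(toy2, "lv", pooled = TRUE), (30 - 20) / 30 * 100)
})

test_that("afterload follows both variants of the Arts formula", {
  expect_equal(afterload(120, 0, 100), 120)
  expect_equal(afterload(120, 50, 100), 300)
  # monotone in LVESV, decreasing in wall volume (product form)
  expect_gt(afterload(120, 60, 100), afterload(120, 50, 100))
  expect_lt(afterload(120, 50, 120), afterload(120, 50, 100))
  # logarithmic variant
  expect_equal(afterload(120, 50, 100, variant = "arts-log"),
               3 * 120 / log(1 + 1.5))
  expect_error(afterload(120, 0, 100, variant = "arts-log"), "LVESV > 0")
  expect_error(afterload(120, 50, 0), "positive")
})

test_that("metric table: EF identity, pose invariance, flagged failures", {
  sim <- coarse_cohort(n = 8)
  mt <- compute_metric_table(sim$shapes, sim$records)
  expect_true(all(mt$ok))
  expect_equal(mt$LVEF, 100 * (mt$LVEDV - mt$LVESV) / mt$LVEDV,
               tolerance = 1e-9)
  expect_equal(mt$RVEF, 100 * (mt$RVEDV - mt$RVESV) / mt$RVEDV,
               tolerance = 1e-9)
  expect_true(all(mt$LVESV > 0 & mt$LVESV < mt$LVEDV))

  # pose invariance of the whole table
  set.seed(4)
  moved <- lapply(sim$shapes, function(s) {
    transform_shape(s, random_rotation(), rnorm(3, 0, 25))
  })
  mt2 <- compute_metric_table(moved, sim$records)
  num <- vapply(mt, is.numeric, logical(1))
  expect_equal(as.data.frame(mt2[num]), as.data.frame(mt[num]),
               tolerance = 1e-9)

  # a broken shape is flagged, not dropped
  broken <- sim$shapes
  broken[[3]]$ed$vertices[1, 1] <- NaN
  mt3 <- compute_metric_table(broken, sim$records)
  expect_equal(nrow(mt3), 8)
  expect_false(mt3$ok[3])
  expect_true(is.na(mt3$LVEDV[3]))
  expect_match(mt3$note[3], "finite")
})

test_that("similarity scaling: strains/EF fixed, lengths scale by s, volumes s^3", {
  tmpl <- coarse_template()
  s <- 1.3
  big <- tmpl
  big$ed <- new_mesh(tmpl$ed$vertices * s, tmpl$ed$faces, validate = FALSE)
  big$es <- new_mesh(tmpl$es$vertices * s, tmpl$es$faces, validate = FALSE)
  lab <- tmpl$labels$surfaces
  expect_equal(gcs_mid(big, "lv"), gcs_mid(tmpl, "lv"), tolerance = 1e-9)
  expect_equal(gls(big, "rv"), gls(tmpl, "rv"), tolerance = 1e-9)
  expect_equal(valve_excursion(big, "mitral"),
               s * valve_excursion(tmpl, "mitral"), tolerance = 1e-9)
  expect_equal(surface_volume(big$ed, lab$lv_endo),
               s^3 * surface_volume(tmpl$ed, lab$lv_endo), tolerance = 1e-9)
})

test_that("planted disease shift is detectable by Wilcoxon on MAPSE", {
  tmpl <- coarse_template()
  mb <- coarse_modes()
  spec <- cohort_spec(
    n_reference = 300, n_disease = c("Heart failure" = 300),
    disease_shift = list("Heart failure" = c(size = 0, motion = -1,
                                             sphericity = 0,
                                             contraction = 0)),
    noise_sd = 0.3, seed = 77)
  sim <- simulate_cohort(tmpl, mb, spec)
  mt <- compute_metric_table(sim$shapes, sim$records)
  dz <- sim$records$group != "Reference"
  w <- wilcoxon_rank_sum(mt$MAPSE[dz], mt$MAPSE[!dz])
  expect_lt(w$p, 0.001)
  expect_lt(mean(mt$MAPSE[dz]), mean(mt$MAPSE[!dz]))
})
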