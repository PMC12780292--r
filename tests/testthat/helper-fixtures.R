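# Shared fixtures, built once per test run. The coarse template keeps the
# mesh small (V ~ 520) so cohort-level tests stay fast; geometry oracles use
# dedicated analytic phantoms instead.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

coarse_template <- function() {
  fixture("coarse_template",
          function() build_template(rings_per_surface = 8, points_per_ring = 16))
}

default_template <- function() {
  fixture("default_template", function() build_template())
}

coarse_modes <- function() {
  fixture("coarse_modes", function() build_mode_bank(coarse_template()))
}

# A small reference-only cohort for atlas/QC tests.
coarse_cohort <- function(n = 60, noise_sd = 0.2, seed = 301) {
  key <- paste("cohort", n, noise_sd, seed)
  fixture(key, function() {
    simulate_cohort(coarse_template(), coarse_modes(),
                    cohort_spec(n_reference = n, n_disease = integer(),
                                noise_sd = noise_sd, seed = seed))
  })
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

transform_shape <- function(shape, R, t) {
  shape$ed <- new_mesh(sweep(shape$ed$vertices %*% R, 2, t, `+`),
                       shape$ed$faces, validate = FALSE)
  shape$es <- new_mesh(sweep(shape$es$vertices %*% R, 2, t, `+`),
                       shape$es$faces, validate = FALSE)
  shape
}
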