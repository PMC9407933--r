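test_that("domain type validation rejects inconsistent inputs", {
  expect_error(anthropometric_profile("x", 175, 139, 145, 84),
               class = "icz_validation_error")
  expect_error(anthropometric_profile("x", -1, 139, 109, 84),
               class = "icz_validation_error")
  expect_error(
    icz_model(test_profile(),
              data.frame(alpha_deg = 0, z_cm = 139, r_cm = 30, force_N = -5)),
    class = "icz_validation_error"
  )
  expect_error(
    icz_model(test_profile(),
              data.frame(alpha_deg = 200, z_cm = 139, r_cm = 30, force_N = 5)),
    class = "icz_validation_error"
  )
  expect_error(simplified_features(0, 10, 10, 10, 10),
               class = "icz_validation_error")
  # declared reach must cover every sample
  expect_error(
    icz_model(test_profile(),
              data.frame(alpha_deg = 0, z_cm = 139, r_cm = c(10, 20, 80),
                         force_N = c(3, 2, 1)),
              reach_boundary = data.frame(alpha_deg = 0, z_cm = 139,
                                          reach_cm = 70)),
    class = "icz_validation_error"
  )
})

test_that("piecewise-linear interpolation reproduces a linear ray exactly", {
  field <- build_strength_field(linear_ray_model())
  expect_equal(field$values[1, 1, ], 200 * (1 - field$r_cm / 70),
               tolerance = 1e-6)
  expect_equal(field$reach[1, 1], 70)
  # interpolation at off-lattice radii is exact too
  rr <- c(12.25, 33.7, 69.99)
  expect_equal(field_value(field, 0, 139, rr), 200 * (1 - rr / 70),
               tolerance = 1e-9)
})

test_that("a non-monotone force dip is corrected like pool-adjacent-violators", {
  model <- icz_model(test_profile(), data.frame(
    alpha_deg = 0, z_cm = 139, r_cm = c(10, 20, 30, 40),
    force_N = c(150, 140, 145, 90)
  ))
  field <- build_strength_field(model)
  expect_equal(pava_nonincreasing_oracle(c(150, 140, 145, 90)),
               c(150, 142.5, 142.5, 90))
  expect_lte(field_value(field, 0, 139, 30), 142.5)
  ray <- field$values[1, 1, ]
  expect_true(all(diff(ray) <= 1e-12))
  # sample values preserved up to the monotonicity correction
  expect_equal(field_value(field, 0, 139, c(10, 20, 30, 40)),
               c(150, 142.5, 142.5, 90), tolerance = 1e-9)
})

test_that("monotone enforcement equals the PAVA oracle and is idempotent", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(3:40, 1)
    y <- cumsum(rnorm(n, -1, 4)) + 100
    fit <- monotone_nonincreasing(y)
    expect_equal(fit, pava_nonincreasing_oracle(y), tolerance = 1e-10)
    expect_equal(monotone_nonincreasing(fit), fit, tolerance = 1e-12)
    expect_true(all(diff(fit) <= 1e-10))
  }
})

test_that("interpolation requires at least 3 distinct radii per ray", {
  model <- icz_model(test_profile(), data.frame(
    alpha_deg = c(0, 0, 0), z_cm = 139, r_cm = c(30, 30, 60),
    force_N = c(100, 102, 50)
  ))
  err <- expect_error(build_strength_field(model),
                      class = "icz_coverage_error")
  expect_match(conditionMessage(err), "alpha=0")
})

test_that("constant-strength layers match closed forms and a dense-scan oracle", {
  field <- build_strength_field(linear_ray_model())
  layer <- extract_constant_strength_layer(field, 100)
  expect_equal(layer$boundary[1, 1], 35)
  expect_false(layer$empty)

  above <- extract_constant_strength_layer(field, 250)
  expect_true(above$empty)
  expect_equal(max(above$boundary), 0)

  expect_error(extract_constant_strength_layer(field, -5),
               class = "icz_validation_error")

  # two rays with different decay rates vs the 0.01 cm dense scan
  s <- rbind(
    data.frame(alpha_deg = 0, z_cm = 139, r_cm = seq(10, 70, 10),
               force_N = 200 * (1 - seq(10, 70, 10) / 70)),
    data.frame(alpha_deg = 60, z_cm = 139, r_cm = seq(10, 60, 10),
               force_N = 150 * (1 - seq(10, 60, 10) / 90))
  )
  m2 <- icz_model(test_profile(), s)
  f2 <- build_strength_field(m2)
  for (level in c(40, 75, 110)) {
    lay <- extract_constant_strength_layer(f2, level)
    i0 <- which(abs(f2$alpha_deg - 0) < 1e-9)
    i60 <- which(abs(f2$alpha_deg - 60) < 1e-9)
    expect_equal(
      lay$boundary[i0, 1],
      dense_scan_boundary_oracle(c(0, 70), c(200, 0), level),
      tolerance = 0.011
    )
    expect_equal(
      lay$boundary[i60, 1],
      min(dense_scan_boundary_oracle(c(0, 90), c(150, 0), level), 60),
      tolerance = 0.011
    )
  }
})

test_that("layers nest and stay within the reach boundary", {
  for (seed in 1:8) {
    field <- random_field(seed)
    levels <- sort(runif(4, 5, max(field$values) * 1.1))
    layers <- lapply(levels, extract_constant_strength_layer, field = field)
    for (i in seq_len(length(layers) - 1L)) {
      expect_true(all(layers[[i + 1L]]$boundary <= layers[[i]]$boundary + 1e-9))
    }
    for (lay in layers) {
      expect_true(all(lay$boundary <= field$reach + 1e-9))
    }
  }
})

test_that("force rescaling is proportional and commutes with layer extraction", {
  field <- build_strength_field(linear_ray_model())
  expect_identical(rescale_forces(field, 1), field)
  expect_error(rescale_forces(field, 0), class = "icz_validation_error")
  expect_error(rescale_forces(field, 1.2), class = "icz_validation_error")

  # k = 0.35 on the linear ray: 0.35 * 200 * (1 - r/70) = 35 at r = 35
  l35 <- extract_constant_strength_layer(rescale_forces(field, 0.35), 35)
  expect_equal(l35$boundary[1, 1], 35, tolerance = 1e-9)

  # bit-for-bit commutation for dyadic k (exact floating-point scaling)
  for (seed in 1:5) {
    f <- random_field(seed + 100)
    for (k in c(0.5, 0.25)) {
      for (L in c(20, 60, 110)) {
        a <- extract_constant_strength_layer(rescale_forces(f, k), k * L)
        b <- extract_constant_strength_layer(f, L)
        expect_identical(a$boundary, b$boundary)
      }
    }
    # arbitrary k agrees to numerical precision
    a <- extract_constant_strength_layer(rescale_forces(f, 0.37), 0.37 * 80)
    b <- extract_constant_strength_layer(f, 80)
    expect_equal(a$boundary, b$boundary, tolerance = 1e-9)
  }
})

test_that("simplified features are extracted at the five defining points", {
  # radially constant field: F1 = F3 = 100 N, D1 = reach
  s <- expand.grid(alpha_deg = c(0, 60), z_cm = c(109, 139),
                   r_cm = c(20, 40, 60))
  s$force_N <- 100
  feats <- extract_simplified_features(icz_model(test_profile(), s))
  expect_equal(as.numeric(feats),
               c(F1 = 100, F2 = 100, F3 = 100, F4 = 100, D1 = 60))

  # missing sagittal shoulder-height ray -> coverage error naming the feature
  s2 <- expand.grid(alpha_deg = 60, z_cm = c(109, 139), r_cm = c(20, 40, 60))
  s2$force_N <- 100
  err <- expect_error(
    extract_simplified_features(icz_model(test_profile(), s2)),
    class = "icz_coverage_error"
  )
  expect_match(conditionMessage(err), "D1")
})

test_that("models round-trip through JSON losslessly", {
  model <- generate_icz(synthetic_spec(test_profile(), 200, 70,
                                       angular_falloff = 0.2,
                                       elbow_ratio = 1.2,
                                       noise_sd_N = 4, seed = 11))
  path <- withr::local_tempfile(fileext = ".json")
  write_icz_model(model, path)
  back <- read_icz_model(path)
  expect_equal(back$profile, model$profile)
  expect_equal(back$samples, model$samples, tolerance = 1e-12)
  expect_equal(back$reach_boundary, model$reach_boundary, tolerance = 1e-12)
  expect_equal(back$side, model$side)
  expect_error(read_icz_model(file.path(tempdir(), "nope.json")),
               class = "icz_schema_error")
})
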