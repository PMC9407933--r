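#' Specification for a synthetic ICZ point cloud
#'
#' Defines a separable, phenomenological strength surface used to generate
#' test and demonstration point clouds without laboratory measurements:
#'
#' `F(alpha, z, r) = peak * angular(alpha) * height(z) * max(0, 1 - r / decay_radius)^p`
#'
#' where `angular(alpha) = max(0, 1 - angular_falloff * |alpha| / 60)` (so
#' `angular_falloff` is the fractional strength loss per 60 degrees away from
#' the sagittal plane), `height(z)` interpolates linearly from `elbow_ratio`
#' at elbow height to 1 at shoulder height (clamped outside), and the radial
#' term decays with exponent `p >= 1`.  `decay_radius_cm` defaults to
#' `reach_cm`, in which case force vanishes exactly at full reach; a larger
#' decay radius leaves a positive residual strength at the reach boundary,
#' as observed in real subjects.
#'
#' @param profile An [anthropometric_profile()].
#' @param peak_force_N Force near the body axis at shoulder height in the
#'   sagittal plane, newtons.
#' @param reach_cm Maximum reach radius (constant over rays), cm.
#' @param decay_exponent Radial decay exponent `p >= 1`.  Default 1.
#' @param angular_falloff Fractional strength loss per 60 degrees, in
#'   `[0, 1]`.  Default 0.
#' @param elbow_ratio Strength at elbow height relative to shoulder height,
#'   `> 0`.  Default 1.
#' @param noise_sd_N Gaussian measurement-noise standard deviation, newtons.
#'   Default 0.
#' @param seed Integer seed for the noise generator.
#' @param decay_radius_cm Radial decay scale, cm.  Default `reach_cm`.
#' @return An object of class `"icz_synthetic_spec"`.
#' @seealso [generate_icz()], [synthetic_spec_from_features()]
#' @export
synthetic_spec <- function(profile, peak_force_N, reach_cm,
                           decay_exponent = 1, angular_falloff = 0,
                           elbow_ratio = 1, noise_sd_N = 0, seed = 1L,
                           decay_radius_cm = reach_cm) {
  if (!inherits(profile, "icz_profile")) {
    icz_validation_error("profile must be an anthropometric_profile()")
  }
  if (!is_num(peak_force_N) || peak_force_N <= 0) {
    icz_validation_error("peak_force_N must be a single positive number")
  }
  if (!is_num(reach_cm) || reach_cm <= 0) {
    icz_validation_error("reach_cm must be a single positive number")
  }
  if (!is_num(decay_radius_cm) || decay_radius_cm < reach_cm) {
    icz_validation_error("decay_radius_cm must be a single number >= reach_cm")
  }
  if (!is_num(decay_exponent) || decay_exponent < 1) {
    icz_validation_error("decay_exponent must be >= 1")
  }
  if (!is_num(angular_falloff) || angular_falloff < 0 || angular_falloff > 1) {
    icz_validation_error("angular_falloff must lie in [0, 1]")
  }
  if (!is_num(elbow_ratio) || elbow_ratio <= 0) {
    icz_validation_error("elbow_ratio must be a single positive number")
  }
  if (!is_num(noise_sd_N) || noise_sd_N < 0) {
    icz_validation_error("noise_sd_N must be >= 0")
  }
  if (!is_num(seed)) icz_validation_error("seed must be a single integer")
  structure(
    list(profile = profile, peak_force_N = peak_force_N, reach_cm = reach_cm,
         decay_exponent = decay_exponent, angular_falloff = angular_falloff,
         elbow_ratio = elbow_ratio, noise_sd_N = noise_sd_N,
         seed = as.integer(seed), decay_radius_cm = decay_radius_cm),
    class = "icz_synthetic_spec"
  )
}

# Noiseless generating surface; used by generate_icz() and by tests as the
# ground truth for round-trip checks.
synthetic_force <- function(spec, alpha, z, r) {
  ang <- pmax(0, 1 - spec$angular_falloff * abs(alpha) / 60)
  sh <- spec$profile$shoulder_height_cm
  el <- spec$profile$elbow_height_cm
  hgt <- stats::approx(c(el, sh), c(spec$elbow_ratio, 1), xout = z,
                       rule = 2)$y
  rad <- pmax(0, 1 - r / spec$decay_radius_cm)^spec$decay_exponent
  spec$peak_force_N * ang * hgt * rad
}

#' Generate a synthetic ICZ point cloud
#'
#' Samples the [synthetic_spec()] surface on a set of measurement rays and
#' returns a full ICZ model.  Deterministic given the spec's seed; the global
#' RNG state is left untouched.  The default sampling (5 angles x 4 heights
#' x 5 radii = 100 points) mirrors the scale of a realistic laboratory
#' protocol.
#'
#' @param spec An [synthetic_spec()].
#' @param alphas_deg Ray angles in degrees.
#' @param z_cm Ray heights in cm; default 4 levels from elbow to shoulder
#'   height.
#' @param points_per_ray Number of radii per ray (equally spaced up to the
#'   reach radius).  At least 3.
#' @return An [icz_model()]; the generating seed is recorded in the model's
#'   metadata.
#' @export
generate_icz <- function(spec,
                         alphas_deg = seq(-60, 60, by = 30),
                         z_cm = NULL,
                         points_per_ray = 5L) {
  if (!inherits(spec, "icz_synthetic_spec")) {
    icz_validation_error("spec must be a synthetic_spec()")
  }
  if (!is_num(points_per_ray) || points_per_ray < 3) {
    icz_validation_error("points_per_ray must be at least 3")
  }
  if (is.null(z_cm)) {
    z_cm <- seq(spec$profile$elbow_height_cm,
                spec$profile$shoulder_height_cm, length.out = 4L)
  }
  pts <- expand.grid(
    r_cm = spec$reach_cm * seq_len(points_per_ray) / points_per_ray,
    z_cm = z_cm,
    alpha_deg = alphas_deg
  )
  force <- synthetic_force(spec, pts$alpha_deg, pts$z_cm, pts$r_cm)
  if (spec$noise_sd_N > 0) {
    force <- force + with_local_seed(spec$seed,
                                     stats::rnorm(length(force), 0,
                                                  spec$noise_sd_N))
    force <- pmax(force, 0)
  }
  samples <- data.frame(
    alpha_deg = pts$alpha_deg, z_cm = pts$z_cm, r_cm = pts$r_cm,
    force_N = force
  )
  model <- icz_model(spec$profile, samples)
  model$metadata <- list(generator = "iczone::generate_icz", seed = spec$seed,
                         noise_sd_N = spec$noise_sd_N)
  model
}

# Run expr under set.seed(seed) without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Solve a synthetic spec that reproduces given simplified features
#'
#' Inverts the generator's closed form so that, with linear radial decay,
#' the noiseless synthetic model reproduces the five target features
#' exactly: `D1` becomes the reach, the decay radius and peak are solved
#' from `F1` (strength at full reach) and `F3` (strength at mid reach),
#' `angular_falloff` from `F2/F1` and `elbow_ratio` from `F4/F1`.
#' Requires `F3 > F1` (strength higher at mid reach than at full reach) and
#' `F2 <= F1`.
#'
#' @param features A [simplified_features()] object (its profile, which must
#'   be present, supplies shoulder and elbow heights).
#' @param noise_sd_N,seed Passed through to [synthetic_spec()].
#' @return An [synthetic_spec()].
#' @examples
#' prof <- anthropometric_profile("subject-7", 175, 139, 109, 84)
#' sp <- synthetic_spec_from_features(
#'   simplified_features(88, 69, 150, 117, 68, profile = prof))
#' as.numeric(extract_simplified_features(generate_icz(sp)))
#' @export
synthetic_spec_from_features <- function(features, noise_sd_N = 0, seed = 1L) {
  if (!inherits(features, "simplified_features")) {
    icz_validation_error("features must be a simplified_features() object")
  }
  if (is.null(features$profile)) {
    icz_validation_error("features must carry a profile (shoulder/elbow heights are needed)")
  }
  F1 <- features$F1_N; F2 <- features$F2_N; F3 <- features$F3_N
  F4 <- features$F4_N; D1 <- features$D1_cm
  if (F3 <= F1) {
    icz_validation_error("need F3 > F1 (mid-reach strength above full-reach strength) to solve the decay radius")
  }
  if (F2 > F1) {
    icz_validation_error("need F2 <= F1 (strength falls off away from the sagittal plane)")
  }
  rho <- F3 / F1
  u <- (rho - 1) / (D1 * (rho - 0.5))   # 1 / decay_radius
  decay_radius <- 1 / u
  peak <- F1 / (1 - D1 * u)
  synthetic_spec(
    profile = features$profile,
    peak_force_N = peak,
    reach_cm = D1,
    decay_exponent = 1,
    angular_falloff = 1 - F2 / F1,
    elbow_ratio = F4 / F1,
    noise_sd_N = noise_sd_N,
    seed = seed,
    decay_radius_cm = decay_radius
  )
}
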