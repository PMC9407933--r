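# Independent oracles used to cross-check the implementation.

# Pool-adjacent-violators for a least-squares monotone NON-INCREASING fit,
# written as the textbook block-merging algorithm (independent of
# stats::isoreg, which the package uses).
pava_nonincreasing_oracle <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n <= 1L) return(y)
  vals <- y[1L]; wts <- w[1L]; sizes <- 1L
  for (i in 2:n) {
    vals <- c(vals, y[i]); wts <- c(wts, w[i]); sizes <- c(sizes, 1L)
    k <- length(vals)
    while (k > 1L && vals[k - 1L] < vals[k]) {
      nv <- (vals[k - 1L] * wts[k - 1L] + vals[k] * wts[k]) /
        (wts[k - 1L] + wts[k])
      vals[k - 1L] <- nv
      wts[k - 1L] <- wts[k - 1L] + wts[k]
      sizes[k - 1L] <- sizes[k - 1L] + sizes[k]
      vals <- vals[-k]; wts <- wts[-k]; sizes <- sizes[-k]
      k <- k - 1L
    }
  }
  rep(vals, sizes)
}

# Brute-force layer boundary: densely scan a piecewise-linear ray profile
# (knots r/f, non-increasing) for the largest radius with force >= level.
dense_scan_boundary_oracle <- function(r, f, level, step = 0.01) {
  grid <- seq(min(r), max(r), by = step)
  vals <- approx(r, f, xout = grid)$y
  hit <- which(vals >= level)
  if (length(hit) == 0L) 0 else grid[hit[length(hit)]]
}

# Random feature tables for property tests.
random_feature_table <- function(n, seed) {
  set.seed(seed)
  feature_table(data.frame(
    entry_id = sprintf("s%03d", seq_len(n)),
    F1_N = runif(n, 20, 120),
    F2_N = runif(n, 20, 100),
    F3_N = runif(n, 40, 230),
    F4_N = runif(n, 25, 155),
    D1_cm = runif(n, 50, 75)
  ))
}

# Exhaustive matcher: normalize everything and take the argmin of the mean
# absolute difference, independent of match_features() internals.
brute_force_best_oracle <- function(table, user_raw) {
  cols <- c("F1_N", "F2_N", "F3_N", "F4_N", "D1_cm")
  lo <- vapply(cols, function(cn) min(table[[cn]]), numeric(1))
  hi <- vapply(cols, function(cn) max(table[[cn]]), numeric(1))
  norm <- function(v) pmin(pmax((v - lo) / (hi - lo), 0), 1)
  u <- norm(user_raw)
  totals <- vapply(seq_len(nrow(table)), function(i) {
    b <- norm(vapply(cols, function(cn) table[[cn]][i], numeric(1)))
    mean(abs(b - u))
  }, numeric(1))
  list(best = table$entry_id[which.min(totals)], totals = totals)
}

test_profile <- function(id = "test-subject") {
  anthropometric_profile(id, 175, 139, 109, 84, age_years = 72)
}

# One-ray model with the linear profile F(r) = 200 * (1 - r / 70).
linear_ray_model <- function(alpha = 0, z = 139, r = seq(10, 70, by = 10)) {
  icz_model(test_profile(), data.frame(
    alpha_deg = alpha, z_cm = z, r_cm = r, force_N = 200 * (1 - r / 70)
  ))
}

# Grid of rays with the same linear radial profile everywhere (constant in
# alpha and z); useful where features at several heights/angles are needed.
linear_grid_model <- function(alphas = c(0, 30, 60), zs = c(109, 139),
                              r = seq(10, 70, by = 10)) {
  s <- expand.grid(alpha_deg = alphas, z_cm = zs, r_cm = r)
  s$force_N <- 200 * (1 - s$r_cm / 70)
  icz_model(test_profile(), s)
}

# Random synthetic field for property tests (noiseless, monotone).
random_field <- function(seed) {
  set.seed(seed)
  spec <- synthetic_spec(
    profile = test_profile(),
    peak_force_N = runif(1, 120, 260),
    reach_cm = runif(1, 55, 80),
    decay_exponent = runif(1, 1, 2.5),
    angular_falloff = runif(1, 0, 0.5),
    elbow_ratio = runif(1, 0.6, 1.4)
  )
  build_strength_field(generate_icz(spec))
}
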