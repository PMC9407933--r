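#' Lattice resolution for strength-field interpolation
#'
#' @param alpha_step_deg Angular step in degrees.  Default 5.
#' @param z_step_cm Height step in centimeters.  Default 5.
#' @param r_step_cm Radial step in centimeters.  Default 1.
#' @return An object of class `"icz_grid_spec"`.
#' @export
grid_spec <- function(alpha_step_deg = 5, z_step_cm = 5, r_step_cm = 1) {
  for (nm in c("alpha_step_deg", "z_step_cm", "r_step_cm")) {
    v <- get(nm)
    if (!is_num(v) || v <= 0) {
      icz_validation_error(sprintf("%s must be a single positive number", nm))
    }
  }
  structure(
    list(alpha_step_deg = alpha_step_deg, z_step_cm = z_step_cm,
         r_step_cm = r_step_cm),
    class = "icz_grid_spec"
  )
}

# Regular sequence lo..hi by step, always containing hi as the last point.
grid_seq <- function(lo, hi, step) {
  if (hi <= lo) return(lo)
  s <- seq(lo, hi, by = step)
  if (s[length(s)] < hi - 1e-9) s <- c(s, hi)
  s
}

#' Enforce a monotone non-increasing sequence
#'
#' Least-squares isotonic (antitonic) regression via [stats::isoreg()] on the
#' negated values.  Used to enforce the physical constraint that the liftable
#' upward force can only decrease with radial distance from the body axis.
#'
#' @param y Numeric vector (values along a ray, in order of increasing
#'   radius).
#' @return Numeric vector of the same length, monotone non-increasing, the
#'   least-squares projection of `y` onto the non-increasing cone.
#' @examples
#' monotone_nonincreasing(c(150, 140, 145, 90))  # -> 150, 142.5, 142.5, 90
#' @export
monotone_nonincreasing <- function(y) {
  if (!is.numeric(y) || anyNA(y)) {
    icz_validation_error("y must be numeric without NA")
  }
  if (length(y) <= 1L) return(y)
  -stats::isoreg(seq_along(y), -y)$yf
}

# Evaluate one measurement ray (monotone-corrected knots r, f) at radii rout.
# Linear between knots; linear continuation of the innermost segment toward
# the body axis (the corrected knots are non-increasing, so this can only
# raise the value); constant beyond the outermost knot (the reach mask zeroes
# anything beyond the ray's reach afterwards).  Floored at zero.
eval_ray <- function(r, f, rout) {
  y <- stats::approx(r, f, xout = pmin(rout, r[length(r)]), rule = 2,
                     ties = "ordered")$y
  lo <- rout < r[1L]
  if (any(lo)) {
    slope <- (f[2L] - f[1L]) / (r[2L] - r[1L])
    y[lo] <- f[1L] + slope * (rout[lo] - r[1L])
  }
  pmax(y, 0)
}

# 1-D linear interpolation weights on a sorted grid: index i and fraction t
# such that u sits between grid[i] and grid[i+1].
lin_weights <- function(u, grid) {
  n <- length(grid)
  if (n == 1L) return(list(i = 1L, t = 0))
  i <- findInterval(u, grid, rightmost.closed = TRUE)
  i <- max(1L, min(i, n - 1L))
  t <- (u - grid[i]) / (grid[i + 1L] - grid[i])
  list(i = i, t = min(max(t, 0), 1))
}

#' Interpolate a strength field from an ICZ force point cloud
#'
#' Builds a regular `(alpha, z, r)` lattice spanning the measured rays and
#' interpolates the maximum upward force at every node.  The scheme is
#' piecewise linear: per ray, sample forces are first projected onto the
#' monotone non-increasing cone (see [monotone_nonincreasing()]) and linearly
#' interpolated in `r`; across rays, bilinear interpolation in `(alpha, z)`
#' when the measured rays form a complete grid, nearest-ray otherwise.  Nodes
#' beyond the interpolated reach boundary carry zero force.
#'
#' @param model An [icz_model()].  Every ray needs at least 3 distinct radii.
#' @param grid An [grid_spec()]; default 5 deg x 5 cm x 1 cm.
#' @return An object of class `"strength_field"` with the lattice axes
#'   (`alpha_deg`, `z_cm`, `r_cm`), a 3-D `values` array of forces in newtons
#'   (dimensions alpha x z x r), and a `reach` matrix (alpha x z) in cm.
#' @seealso [field_value()], [reach_at()], [extract_constant_strength_layer()]
#' @export
build_strength_field <- function(model, grid = grid_spec()) {
  if (!inherits(model, "icz_model")) {
    icz_validation_error("model must be an icz_model")
  }
  if (!inherits(grid, "icz_grid_spec")) {
    icz_validation_error("grid must be a grid_spec()")
  }
  s <- model$samples
  key <- paste(s$alpha_deg, s$z_cm, sep = "|")
  rays_raw <- split(s, key)

  for (ray in rays_raw) {
    ndist <- length(unique(ray$r_cm))
    if (ndist < 3L) {
      icz_coverage_error(sprintf(
        "ray (alpha=%g deg, z=%g cm) has only %d distinct radii; at least 3 are required for interpolation",
        ray$alpha_deg[1L], ray$z_cm[1L], ndist
      ))
    }
  }

  rb <- model$reach_boundary
  rb_key <- paste(rb$alpha_deg, rb$z_cm, sep = "|")

  rays <- lapply(rays_raw, function(ray) {
    agg <- stats::aggregate(force_N ~ r_cm, data = ray, FUN = mean)
    agg <- agg[order(agg$r_cm), , drop = FALSE]
    list(
      alpha = ray$alpha_deg[1L],
      z = ray$z_cm[1L],
      r = agg$r_cm,
      f = monotone_nonincreasing(agg$force_N),
      reach = rb$reach_cm[match(paste(ray$alpha_deg[1L], ray$z_cm[1L],
                                      sep = "|"), rb_key)]
    )
  })

  ray_alpha <- vapply(rays, `[[`, numeric(1), "alpha")
  ray_z <- vapply(rays, `[[`, numeric(1), "z")
  ray_reach <- vapply(rays, `[[`, numeric(1), "reach")
  ua <- sort(unique(ray_alpha))
  uz <- sort(unique(ray_z))

  alpha_grid <- grid_seq(min(ua), max(ua), grid$alpha_step_deg)
  z_grid <- grid_seq(min(uz), max(uz), grid$z_step_cm)
  r_grid <- grid_seq(0, max(ray_reach), grid$r_step_cm)

  # ray index by (alpha, z) position when the rays form a complete grid
  complete <- length(rays) == length(ua) * length(uz)
  if (complete) {
    ray_index <- matrix(NA_integer_, length(ua), length(uz))
    ia <- match(ray_alpha, ua)
    iz <- match(ray_z, uz)
    ray_index[cbind(ia, iz)] <- seq_along(rays)
    complete <- !anyNA(ray_index)
  }

  # per-ray evaluation on the radial grid (monotone by construction)
  E <- t(vapply(rays, function(ray) eval_ray(ray$r, ray$f, r_grid),
                numeric(length(r_grid))))

  na <- length(alpha_grid)
  nz <- length(z_grid)
  nr <- length(r_grid)
  values <- array(0, dim = c(na, nz, nr))
  reach_mat <- matrix(0, na, nz)

  for (iz in seq_len(nz)) {
    for (ia in seq_len(na)) {
      if (complete) {
        wa <- lin_weights(alpha_grid[ia], ua)
        wz <- lin_weights(z_grid[iz], uz)
        idx <- c(ray_index[wa$i, wz$i],
                 if (length(ua) > 1L) ray_index[wa$i + 1L, wz$i],
                 if (length(uz) > 1L) ray_index[wa$i, wz$i + 1L],
                 if (length(ua) > 1L && length(uz) > 1L)
                   ray_index[wa$i + 1L, wz$i + 1L])
        w <- c((1 - wa$t) * (1 - wz$t),
               if (length(ua) > 1L) wa$t * (1 - wz$t),
               if (length(uz) > 1L) (1 - wa$t) * wz$t,
               if (length(ua) > 1L && length(uz) > 1L) wa$t * wz$t)
      } else {
        d2 <- ((alpha_grid[ia] - ray_alpha) / grid$alpha_step_deg)^2 +
          ((z_grid[iz] - ray_z) / grid$z_step_cm)^2
        idx <- which.min(d2)
        w <- 1
      }
      reach_here <- sum(w * ray_reach[idx])
      v <- drop(w %*% E[idx, , drop = FALSE])
      v[r_grid > reach_here + 1e-9] <- 0
      values[ia, iz, ] <- v
      reach_mat[ia, iz] <- reach_here
    }
  }

  structure(
    list(
      alpha_deg = alpha_grid,
      z_cm = z_grid,
      r_cm = r_grid,
      values = values,
      reach = reach_mat,
      source_id = model$profile$subject_id,
      grid = grid
    ),
    class = "strength_field"
  )
}

#' @export
print.strength_field <- function(x, ...) {
  cat(sprintf(
    "Strength field '%s': lattice %d x %d x %d (alpha %g..%g deg, z %g..%g cm, r 0..%g cm), force 0..%g N\n",
    x$source_id, length(x$alpha_deg), length(x$z_cm), length(x$r_cm),
    min(x$alpha_deg), max(x$alpha_deg), min(x$z_cm), max(x$z_cm),
    max(x$r_cm), max(x$values)
  ))
  invisible(x)
}

in_extent <- function(u, grid, tol = 1e-8) {
  u >= grid[1L] - tol && u <= grid[length(grid)] + tol
}

#' Evaluate a strength field at arbitrary points
#'
#' Trilinear interpolation of the lattice force values.  Points outside the
#' field's angular or height extent return `NA`; radii beyond the lattice
#' return 0 N.
#'
#' @param field A `"strength_field"`.
#' @param alpha,z,r Numeric vectors (recycled) of cylindrical coordinates:
#'   degrees, cm, cm.
#' @return Numeric vector of forces in newtons.
#' @export
field_value <- function(field, alpha, z, r) {
  stopifnot(inherits(field, "strength_field"))
  n <- max(length(alpha), length(z), length(r))
  alpha <- rep_len(alpha, n)
  z <- rep_len(z, n)
  r <- rep_len(r, n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    if (!in_extent(alpha[k], field$alpha_deg) || !in_extent(z[k], field$z_cm)) {
      out[k] <- NA_real_
      next
    }
    if (r[k] < 0) icz_validation_error("radii must be >= 0")
    if (r[k] > field$r_cm[length(field$r_cm)] + 1e-9) {
      out[k] <- 0
      next
    }
    wa <- lin_weights(alpha[k], field$alpha_deg)
    wz <- lin_weights(z[k], field$z_cm)
    wr <- lin_weights(r[k], field$r_cm)
    acc <- 0
    for (da in 0:1) {
      pa <- if (da == 0) 1 - wa$t else wa$t
      if (pa == 0 && length(field$alpha_deg) > 1L) next
      ia <- min(wa$i + da, length(field$alpha_deg))
      for (dz in 0:1) {
        pz <- if (dz == 0) 1 - wz$t else wz$t
        if (pz == 0 && length(field$z_cm) > 1L) next
        iz <- min(wz$i + dz, length(field$z_cm))
        for (dr in 0:1) {
          pr <- if (dr == 0) 1 - wr$t else wr$t
          if (pr == 0 && length(field$r_cm) > 1L) next
          ir <- min(wr$i + dr, length(field$r_cm))
          if (length(field$alpha_deg) == 1L && da == 1) next
          if (length(field$z_cm) == 1L && dz == 1) next
          if (length(field$r_cm) == 1L && dr == 1) next
          acc <- acc + pa * pz * pr * field$values[ia, iz, ir]
        }
      }
    }
    out[k] <- acc
  }
  out
}

#' Reach boundary of a strength field
#'
#' Bilinear interpolation of the per-ray maximum reach radius.  Points outside
#' the field's angular or height extent return `NA`.
#'
#' @param field A `"strength_field"`.
#' @param alpha,z Numeric vectors (recycled): degrees, cm.
#' @return Numeric vector of reach radii in cm.
#' @export
reach_at <- function(field, alpha, z) {
  stopifnot(inherits(field, "strength_field"))
  n <- max(length(alpha), length(z))
  alpha <- rep_len(alpha, n)
  z <- rep_len(z, n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    if (!in_extent(alpha[k], field$alpha_deg) || !in_extent(z[k], field$z_cm)) {
      out[k] <- NA_real_
      next
    }
    wa <- lin_weights(alpha[k], field$alpha_deg)
    wz <- lin_weights(z[k], field$z_cm)
    i2 <- min(wa$i + 1L, length(field$alpha_deg))
    j2 <- min(wz$i + 1L, length(field$z_cm))
    out[k] <- (1 - wa$t) * (1 - wz$t) * field$reach[wa$i, wz$i] +
      wa$t * (1 - wz$t) * field$reach[i2, wz$i] +
      (1 - wa$t) * wz$t * field$reach[wa$i, j2] +
      wa$t * wz$t * field$reach[i2, j2]
  }
  out
}
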