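#' Extract a constant-strength layer from a field
#'
#' A constant-strength layer at level `L` is the outer boundary of the region
#' in which the person can exert at least `L` newtons upward: per lattice ray
#' `(alpha, z)`, the largest radius at which the (piecewise-linear) field
#' still reaches `L`, capped at the reach boundary.  Objects requiring a lift
#' force of `L` should be placed inside this layer.
#'
#' Layers nest: for `L1 < L2` the `L2` boundary lies inside the `L1` boundary
#' on every ray.
#'
#' @param field A `"strength_field"`.
#' @param level Force level in newtons, `> 0`.
#' @return An object of class `"strength_layer"`: the `level`, the lattice
#'   axes `alpha_deg` / `z_cm`, a `boundary` matrix of radii in cm (0 where
#'   the level is never reached) and an `empty` flag (`TRUE` when the level
#'   exceeds the field's global maximum).
#' @seealso [layer_mesh()], [rescale_forces()]
#' @export
extract_constant_strength_layer <- function(field, level) {
  stopifnot(inherits(field, "strength_field"))
  if (!is_num(level) || level <= 0) {
    icz_validation_error("level must be a single positive force in newtons")
  }
  na <- length(field$alpha_deg)
  nz <- length(field$z_cm)
  r <- field$r_cm
  boundary <- matrix(0, na, nz)
  for (iz in seq_len(nz)) {
    for (ia in seq_len(na)) {
      v <- field$values[ia, iz, ]
      hit <- which(v >= level)
      if (length(hit) == 0L) next
      i <- hit[length(hit)]
      if (i == length(v)) {
        b <- r[i]
      } else {
        # linear crossing between the last node at >= level and the next
        b <- r[i] + (v[i] - level) / (v[i] - v[i + 1L]) * (r[i + 1L] - r[i])
      }
      boundary[ia, iz] <- min(b, field$reach[ia, iz])
    }
  }
  structure(
    list(
      level = level,
      alpha_deg = field$alpha_deg,
      z_cm = field$z_cm,
      boundary = boundary,
      empty = level > max(field$values),
      source_id = field$source_id
    ),
    class = "strength_layer"
  )
}

#' @export
print.strength_layer <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("Constant-strength layer at %g N: empty (level exceeds the field maximum)\n",
                x$level))
  } else {
    cat(sprintf(
      "Constant-strength layer at %g N: boundary radii %g..%g cm over %d x %d rays\n",
      x$level, min(x$boundary), max(x$boundary),
      length(x$alpha_deg), length(x$z_cm)
    ))
  }
  invisible(x)
}

#' Layer boundary radius at arbitrary angles and heights
#'
#' Bilinear interpolation of the layer's boundary matrix.  Points outside the
#' layer's angular or height extent return `NA`.
#'
#' @param layer A `"strength_layer"`.
#' @param alpha,z Numeric vectors (recycled): degrees, cm.
#' @return Numeric vector of boundary radii in cm (0 where the layer's force
#'   level is never reached).
#' @export
layer_boundary_at <- function(layer, alpha, z) {
  stopifnot(inherits(layer, "strength_layer"))
  n <- max(length(alpha), length(z))
  alpha <- rep_len(alpha, n)
  z <- rep_len(z, n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    if (!in_extent(alpha[k], layer$alpha_deg) || !in_extent(z[k], layer$z_cm)) {
      out[k] <- NA_real_
      next
    }
    wa <- lin_weights(alpha[k], layer$alpha_deg)
    wz <- lin_weights(z[k], layer$z_cm)
    i2 <- min(wa$i + 1L, length(layer$alpha_deg))
    j2 <- min(wz$i + 1L, length(layer$z_cm))
    out[k] <- (1 - wa$t) * (1 - wz$t) * layer$boundary[wa$i, wz$i] +
      wa$t * (1 - wz$t) * layer$boundary[i2, wz$i] +
      (1 - wa$t) * wz$t * layer$boundary[wa$i, j2] +
      wa$t * wz$t * layer$boundary[i2, j2]
  }
  out
}

#' Rescale limit forces to allowable working forces
#'
#' Laboratory-measured limit forces `F` are reduced to allowable forces
#' `F_d = k * F` to account for practical working conditions (convenience,
#' load duration, load-holding time).  The rescaling is proportional and does
#' not change the geometry: the layer of the rescaled field at level `k * L`
#' coincides with the layer of the original field at level `L`.
#'
#' @param x A `"strength_field"` or `"strength_layer"`.
#' @param k Correction factor in `(0, 1]`.  Default 1 (no correction).
#' @return An object of the same class with all force values multiplied by
#'   `k` (for a layer, its level; the boundary geometry is untouched).
#' @export
rescale_forces <- function(x, k = 1) {
  if (!is_num(k) || k <= 0 || k > 1) {
    icz_validation_error("k must be a single number in (0, 1]")
  }
  UseMethod("rescale_forces")
}

#' @export
rescale_forces.strength_field <- function(x, k = 1) {
  x$values <- x$values * k
  x
}

#' @export
rescale_forces.strength_layer <- function(x, k = 1) {
  x$level <- x$level * k
  x
}

#' @export
rescale_forces.default <- function(x, k = 1) {
  icz_validation_error("rescale_forces() expects a strength_field or strength_layer")
}

#' Extract the five-feature simplified characterization from a full model
#'
#' The simplified model reduces a full ICZ to five quickly measurable values:
#' \describe{
#'   \item{D1_cm}{anterior reach in the sagittal plane (alpha = 0) at
#'     shoulder height;}
#'   \item{F1_N}{upward strength at full reach `D1`, shoulder height,
#'     alpha = 0;}
#'   \item{F2_N}{upward strength at full reach, shoulder height, alpha = 60
#'     degrees;}
#'   \item{F3_N}{upward strength at mid-reach `D1/2`, shoulder height,
#'     alpha = 0;}
#'   \item{F4_N}{upward strength at full reach, elbow height, alpha = 0.}
#' }
#'
#' @param model An [icz_model()] whose profile carries shoulder and elbow
#'   heights and whose samples cover the rays above.
#' @param grid An [grid_spec()] used to build the interpolated field.
#' @return A [simplified_features()] object carrying the model's profile.
#' @export
extract_simplified_features <- function(model, grid = grid_spec()) {
  field <- build_strength_field(model, grid)
  sh <- model$profile$shoulder_height_cm
  el <- model$profile$elbow_height_cm

  requirement <- list(
    D1 = c(0, sh), F1 = c(0, sh), F3 = c(0, sh),
    F2 = c(60, sh), F4 = c(0, el)
  )
  missing <- names(requirement)[!vapply(requirement, function(p) {
    in_extent(p[1L], field$alpha_deg) && in_extent(p[2L], field$z_cm)
  }, logical(1))]
  if (length(missing) > 0L) {
    icz_coverage_error(sprintf(
      "model does not cover the ray(s) required for feature(s) %s (field extent: alpha %g..%g deg, z %g..%g cm)",
      paste(missing, collapse = ", "),
      min(field$alpha_deg), max(field$alpha_deg),
      min(field$z_cm), max(field$z_cm)
    ))
  }

  D1 <- reach_at(field, 0, sh)
  F1 <- field_value(field, 0, sh, D1)
  F2 <- field_value(field, 60, sh, reach_at(field, 60, sh))
  F3 <- field_value(field, 0, sh, D1 / 2)
  F4 <- field_value(field, 0, el, reach_at(field, 0, el))

  simplified_features(F1, F2, F3, F4, D1, profile = model$profile)
}

#' Five-feature simplified model of a user
#'
#' @param F1_N,F2_N,F3_N,F4_N Strength values in newtons (see
#'   [extract_simplified_features()] for the measurement points).
#' @param D1_cm Anterior reach at shoulder height in cm.
#' @param profile Optional [anthropometric_profile()].
#' @return An object of class `"simplified_features"`.
#' @export
simplified_features <- function(F1_N, F2_N, F3_N, F4_N, D1_cm, profile = NULL) {
  vals <- c(F1_N = F1_N, F2_N = F2_N, F3_N = F3_N, F4_N = F4_N, D1_cm = D1_cm)
  if (!is.numeric(vals) || length(vals) != 5L || anyNA(vals) ||
      any(!is.finite(vals))) {
    icz_validation_error("all five feature values must be finite numbers")
  }
  if (any(vals <= 0)) {
    icz_validation_error("all five feature values must be strictly positive")
  }
  if (!is.null(profile) && !inherits(profile, "icz_profile")) {
    icz_validation_error("profile must be an anthropometric_profile() or NULL")
  }
  structure(
    list(F1_N = F1_N, F2_N = F2_N, F3_N = F3_N, F4_N = F4_N, D1_cm = D1_cm,
         profile = profile),
    class = "simplified_features"
  )
}

#' @export
print.simplified_features <- function(x, ...) {
  cat(sprintf(
    "Simplified features: F1 = %g N, F2 = %g N, F3 = %g N, F4 = %g N, D1 = %g cm\n",
    x$F1_N, x$F2_N, x$F3_N, x$F4_N, x$D1_cm
  ))
  invisible(x)
}

#' @export
as.double.simplified_features <- function(x, ...) {
  c(F1 = x$F1_N, F2 = x$F2_N, F3 = x$F3_N, F4 = x$F4_N, D1 = x$D1_cm)
}

#' @export
as.numeric.simplified_features <- as.double.simplified_features
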