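#' Full ICZ model: force point cloud plus anthropometric profile
#'
#' An individual convenient zone (ICZ) model is a subject's complete
#' spatial-strength characteristic: a cloud of maximum upward-force
#' measurements in a body-centered cylindrical frame, together with the
#' subject's anthropometric profile.  The frame has `alpha_deg` as the
#' horizontal angle about the vertical body axis (0 = sagittal plane, positive
#' toward the measured limb's side), `z_cm` the height above the floor and
#' `r_cm` the radial distance from the body axis.
#'
#' Measurements are taken along rays: fixed `(alpha, z)` pairs with several
#' radii each.  The reach boundary (maximum attainable radius per ray) is
#' taken as the largest measured radius on each ray unless supplied
#' explicitly.
#'
#' @param profile An [anthropometric_profile()].
#' @param samples Data frame with numeric columns `alpha_deg`, `z_cm`, `r_cm`,
#'   `force_N` (maximum upward force, newtons).
#' @param reach_boundary Optional data frame `alpha_deg`, `z_cm`, `reach_cm`
#'   giving the maximum reach radius per measured ray.  Must cover every
#'   sampled ray.  Default: derived as the largest measured radius per ray.
#' @param side Which limb the zone describes, `"right"` or `"left"`.  Stored
#'   as metadata only; no geometric mirroring is applied.
#' @param d1_convention How anterior reach is measured, `"handgrip"` (to the
#'   handgrip axis) or `"fingertip"`.  Stored as metadata.
#'
#' @return An object of class `"icz_model"`.
#' @seealso [build_strength_field()], [extract_simplified_features()],
#'   [generate_icz()]
#' @export
icz_model <- function(profile, samples, reach_boundary = NULL,
                      side = c("right", "left"),
                      d1_convention = c("handgrip", "fingertip")) {
  side <- match.arg(side)
  d1_convention <- match.arg(d1_convention)
  if (!inherits(profile, "icz_profile")) {
    icz_validation_error("profile must be an anthropometric_profile()")
  }
  samples <- validate_samples(samples)

  derived <- derive_reach_boundary(samples)
  if (is.null(reach_boundary)) {
    reach_boundary <- derived
  } else {
    reach_boundary <- validate_reach_boundary(reach_boundary, derived)
  }

  structure(
    list(
      profile = profile,
      samples = samples,
      reach_boundary = reach_boundary,
      side = side,
      d1_convention = d1_convention,
      metadata = list()
    ),
    class = "icz_model"
  )
}

validate_samples <- function(samples) {
  need <- c("alpha_deg", "z_cm", "r_cm", "force_N")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    icz_validation_error(paste0(
      "samples must be a data frame with columns ",
      paste(need, collapse = ", ")
    ))
  }
  if (nrow(samples) == 0L) icz_validation_error("samples must be non-empty")
  samples <- samples[need]
  for (nm in need) {
    if (!is.numeric(samples[[nm]]) || anyNA(samples[[nm]]) ||
        any(!is.finite(samples[[nm]]))) {
      icz_validation_error(sprintf("samples$%s must be finite numeric", nm))
    }
  }
  if (any(samples$force_N < 0)) {
    icz_validation_error("sample forces must be >= 0 N")
  }
  if (any(samples$r_cm < 0)) {
    icz_validation_error("sample radii must be >= 0 cm")
  }
  if (any(samples$alpha_deg < -180 | samples$alpha_deg > 180)) {
    icz_validation_error("sample angles must lie in [-180, 180] degrees")
  }
  rownames(samples) <- NULL
  samples
}

derive_reach_boundary <- function(samples) {
  agg <- stats::aggregate(r_cm ~ alpha_deg + z_cm, data = samples, FUN = max)
  names(agg)[names(agg) == "r_cm"] <- "reach_cm"
  agg <- agg[order(agg$alpha_deg, agg$z_cm), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

validate_reach_boundary <- function(reach_boundary, derived, tol = 1e-6) {
  need <- c("alpha_deg", "z_cm", "reach_cm")
  if (!is.data.frame(reach_boundary) || !all(need %in% names(reach_boundary))) {
    icz_validation_error(
      "reach_boundary must be a data frame with columns alpha_deg, z_cm, reach_cm"
    )
  }
  reach_boundary <- reach_boundary[need]
  key_b <- paste(reach_boundary$alpha_deg, reach_boundary$z_cm)
  key_d <- paste(derived$alpha_deg, derived$z_cm)
  missing <- setdiff(key_d, key_b)
  if (length(missing) > 0L) {
    icz_validation_error(sprintf(
      "reach_boundary is missing sampled ray(s): (alpha, z) = %s",
      paste(missing, collapse = "; ")
    ))
  }
  # every sample must lie within its ray's declared reach
  m <- match(key_d, key_b)
  if (any(derived$reach_cm > reach_boundary$reach_cm[m] + tol)) {
    bad <- which(derived$reach_cm > reach_boundary$reach_cm[m] + tol)[1L]
    icz_validation_error(sprintf(
      "sample at (alpha=%g, z=%g) lies at r=%g cm beyond the declared reach %g cm",
      derived$alpha_deg[bad], derived$z_cm[bad], derived$reach_cm[bad],
      reach_boundary$reach_cm[m][bad]
    ))
  }
  reach_boundary <- reach_boundary[order(reach_boundary$alpha_deg,
                                         reach_boundary$z_cm), , drop = FALSE]
  rownames(reach_boundary) <- NULL
  reach_boundary
}

#' @export
print.icz_model <- function(x, ...) {
  nray <- nrow(unique(x$samples[c("alpha_deg", "z_cm")]))
  cat(sprintf(
    "ICZ model for subject '%s' (%s limb): %d force samples on %d rays,\n  alpha %g..%g deg, z %g..%g cm, max reach %g cm, max force %g N\n",
    x$profile$subject_id, x$side, nrow(x$samples), nray,
    min(x$samples$alpha_deg), max(x$samples$alpha_deg),
    min(x$samples$z_cm), max(x$samples$z_cm),
    max(x$reach_boundary$reach_cm), max(x$samples$force_N)
  ))
  invisible(x)
}

ICZ_MODEL_SCHEMA_VERSION <- 1L

#' Read and write ICZ models as JSON
#'
#' The on-disk format is a versioned JSON object with fields `schema_version`,
#' `profile`, `samples` (records with `alpha_deg`, `z_cm`, `r_cm`, `force_N`),
#' `reach_boundary`, `side`, `d1_convention` and free-form `metadata`.
#'
#' @param model An [icz_model()].
#' @param path File path.
#' @return `read_icz_model()` returns an `"icz_model"`; `write_icz_model()`
#'   returns `path` invisibly.
#' @export
write_icz_model <- function(model, path) {
  if (!inherits(model, "icz_model")) {
    icz_validation_error("model must be an icz_model")
  }
  obj <- list(
    schema_version = ICZ_MODEL_SCHEMA_VERSION,
    profile = unclass(model$profile),
    side = model$side,
    d1_convention = model$d1_convention,
    samples = model$samples,
    reach_boundary = model$reach_boundary,
    metadata = model$metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_icz_model
#' @export
read_icz_model <- function(path) {
  if (!file.exists(path)) {
    icz_schema_error(sprintf("model file not found: %s", path))
  }
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) icz_schema_error(sprintf("cannot parse %s: %s",
                                                 path, conditionMessage(e)))
  )
  if (is.null(obj$schema_version) ||
      obj$schema_version != ICZ_MODEL_SCHEMA_VERSION) {
    icz_schema_error(sprintf(
      "%s: unsupported or missing schema_version (expected %d)",
      path, ICZ_MODEL_SCHEMA_VERSION
    ))
  }
  p <- obj$profile
  for (nm in c("subject_id", "body_height_cm", "shoulder_height_cm",
               "elbow_height_cm", "body_mass_kg")) {
    if (is.null(p[[nm]])) {
      icz_schema_error(sprintf("%s: profile is missing field '%s'", path, nm))
    }
  }
  profile <- anthropometric_profile(
    subject_id = p$subject_id,
    body_height_cm = p$body_height_cm,
    shoulder_height_cm = p$shoulder_height_cm,
    elbow_height_cm = p$elbow_height_cm,
    body_mass_kg = p$body_mass_kg,
    age_years = p$age_years,
    notes = p$notes
  )
  model <- icz_model(
    profile = profile,
    samples = as.data.frame(obj$samples),
    reach_boundary = if (is.null(obj$reach_boundary)) NULL
                     else as.data.frame(obj$reach_boundary),
    side = if (is.null(obj$side)) "right" else obj$side,
    d1_convention = if (is.null(obj$d1_convention)) "handgrip"
                    else obj$d1_convention
  )
  if (!is.null(obj$metadata) && length(obj$metadata) > 0L) {
    model$metadata <- obj$metadata
  }
  model
}
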