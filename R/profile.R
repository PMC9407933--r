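#' Anthropometric profile of a subject
#'
#' Bundles the body dimensions that anchor an individual convenient zone (ICZ)
#' model: overall stature, shoulder and elbow heights (the two working heights
#' at which limb strength is characterized) and body mass.  Heights are
#' measured from the floor in the standing posture in which the zone was
#' measured.
#'
#' @param subject_id Character identifier for the subject.
#' @param body_height_cm Stature in centimeters.
#' @param shoulder_height_cm Shoulder (acromial) height in centimeters.
#' @param elbow_height_cm Elbow height in centimeters.
#' @param body_mass_kg Body mass in kilograms.
#' @param age_years Optional age in years.
#' @param notes Optional free-text notes (posture, limb side particulars).
#'
#' @return An object of class `"icz_profile"`.
#' @examples
#' anthropometric_profile("senior-01", 175, 139, 109, 84, age_years = 72)
#' @export
anthropometric_profile <- function(subject_id,
                                   body_height_cm,
                                   shoulder_height_cm,
                                   elbow_height_cm,
                                   body_mass_kg,
                                   age_years = NULL,
                                   notes = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id)) {
    icz_validation_error("subject_id must be a non-empty character scalar")
  }
  for (nm in c("body_height_cm", "shoulder_height_cm", "elbow_height_cm",
               "body_mass_kg")) {
    v <- get(nm)
    if (!is_num(v) || v <= 0) {
      icz_validation_error(sprintf("%s must be a single positive number", nm))
    }
  }
  if (!is.null(age_years) && (!is_num(age_years) || age_years <= 0)) {
    icz_validation_error("age_years must be a single positive number or NULL")
  }
  if (!(elbow_height_cm < shoulder_height_cm && shoulder_height_cm < body_height_cm)) {
    icz_validation_error(
      "heights must satisfy elbow_height_cm < shoulder_height_cm < body_height_cm"
    )
  }
  structure(
    list(
      subject_id = subject_id,
      body_height_cm = body_height_cm,
      shoulder_height_cm = shoulder_height_cm,
      elbow_height_cm = elbow_height_cm,
      body_mass_kg = body_mass_kg,
      age_years = age_years,
      notes = notes
    ),
    class = "icz_profile"
  )
}

#' @export
print.icz_profile <- function(x, ...) {
  cat(sprintf(
    "Anthropometric profile '%s': height %g cm (shoulder %g, elbow %g), mass %g kg%s\n",
    x$subject_id, x$body_height_cm, x$shoulder_height_cm, x$elbow_height_cm,
    x$body_mass_kg,
    if (is.null(x$age_years)) "" else sprintf(", age %g", x$age_years)
  ))
  invisible(x)
}
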