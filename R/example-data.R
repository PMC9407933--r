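#' Bundled similarity worksheet: 12-subject repository and example user
#'
#' The package ships a complete worked example used throughout the
#' documentation and the validation suite: a repository of twelve laboratory
#' subjects' five-feature characterizations, an example user (a 72-year-old,
#' 175 cm, 84 kg senior with shoulder height 139 cm and elbow height 109 cm)
#' measured with the simplified protocol, the user's normalized feature
#' vector, and the reference per-feature and total similarity scores of all
#' twelve entries against that user (3-decimal display precision).
#'
#' Note an internal inconsistency of the worksheet, preserved as shipped: the
#' user's raw F4 is 110 N, but the normalized f4 = 0.739 corresponds to
#' 118 N under min-max normalization with bounds (30, 149).  The reference
#' scores follow the normalized row; matching from raw features instead gives
#' entry 7 a total of about 0.095 rather than 0.085 (entry 7 remains the best
#' match either way).  Both input paths are supported by [match_features()].
#'
#' @return A list with components:
#' \describe{
#'   \item{table}{[feature_table()] of the 12 repository entries (ids "1" to
#'     "12").}
#'   \item{user}{[simplified_features()] raw measurements (71, 57, 146,
#'     110 N; 68 cm) with the user's profile.}
#'   \item{user_normalized}{[normalized_features()] as printed: (0.564,
#'     0.485, 0.557, 0.739, 0.824).}
#'   \item{bounds_reference}{Published per-feature min/max rows.}
#'   \item{similarity_reference}{Data frame of the reference per-feature
#'     scores and totals (columns `entry_id`, `sim_f1` ... `sim_d1`,
#'     `total`).}
#'   \item{best_id}{The reference best-matching entry, `"7"`.}
#' }
#' @examples
#' ws <- example_worksheet()
#' match_features(ws$table, ws$user_normalized)
#' @export
example_worksheet <- function() {
  table <- feature_table(data.frame(
    entry_id = as.character(1:12),
    F1_N = c(62, 82, 64, 63, 66, 27, 88, 87, 87, 105, 81, 57),
    F2_N = c(50, 62, 52, 64, 75, 24, 69, 86, 79, 92, 79, 45),
    F3_N = c(125, 154, 170, 90, 94, 49, 150, 115, 167, 223, 102, 141),
    F4_N = c(85, 118, 83, 80, 77, 30, 117, 105, 99, 149, 103, 69),
    D1_cm = c(71, 54, 66, 67, 55, 70, 68, 58, 57, 65, 68, 67)
  ))

  user_profile <- anthropometric_profile(
    subject_id = "example-user",
    body_height_cm = 175, shoulder_height_cm = 139, elbow_height_cm = 109,
    body_mass_kg = 84, age_years = 72
  )
  user <- simplified_features(71, 57, 146, 110, 68, profile = user_profile)
  user_normalized <- normalized_features(0.564, 0.485, 0.557, 0.739, 0.824)

  bounds_reference <- data.frame(
    feature = c("F1", "F2", "F3", "F4", "D1"),
    min_value = c(27, 24, 49, 30, 54),
    max_value = c(105, 92, 223, 149, 71)
  )

  similarity_reference <- data.frame(
    entry_id = as.character(1:12),
    sim_f1 = c(0.115, 0.141, 0.090, 0.102, 0.064, 0.564, 0.218, 0.205, 0.205,
               0.436, 0.128, 0.179),
    sim_f2 = c(0.103, 0.074, 0.073, 0.103, 0.265, 0.485, 0.177, 0.427, 0.324,
               0.515, 0.324, 0.176),
    sim_f3 = c(0.120, 0.046, 0.138, 0.321, 0.298, 0.557, 0.023, 0.178, 0.121,
               0.443, 0.252, 0.028),
    sim_f4 = c(0.277, 0.000, 0.294, 0.319, 0.344, 0.739, 0.008, 0.109, 0.159,
               0.261, 0.126, 0.411),
    sim_d1 = c(0.176, 0.824, 0.118, 0.059, 0.765, 0.117, 0.000, 0.589, 0.648,
               0.177, 0.000, 0.059),
    total = c(0.158, 0.217, 0.143, 0.181, 0.347, 0.492, 0.085, 0.302, 0.291,
              0.366, 0.166, 0.171)
  )

  list(
    table = table,
    user = user,
    user_normalized = user_normalized,
    bounds_reference = bounds_reference,
    similarity_reference = similarity_reference,
    best_id = "7"
  )
}
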