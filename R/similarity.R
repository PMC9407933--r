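#' Min-max normalization of a feature value
#'
#' Maps a raw feature value onto `[0, 1]` relative to the repository bounds
#' for that feature:
#' `a = (A - A_min) / (A_max - A_min)`.
#'
#' Values outside the bounds are clamped to `[0, 1]` with a warning (class
#' `"icz_clamp_warning"`).  Degenerate bounds (`A_max == A_min`) yield 0 with
#' a warning (class `"icz_degenerate_bounds_warning"`).
#'
#' @param value Numeric vector of raw feature values.
#' @param min_value,max_value Scalar bounds for this feature.
#' @return Numeric vector of normalized values in `[0, 1]`.
#' @examples
#' normalize_feature(71, 27, 105)  # 0.564 at 3 decimals
#' @export
normalize_feature <- function(value, min_value, max_value) {
  if (!is.numeric(value) || anyNA(value)) {
    icz_validation_error("value must be numeric without NA")
  }
  if (!is_num(min_value) || !is_num(max_value) || max_value < min_value) {
    icz_validation_error("bounds must be single numbers with max_value >= min_value")
  }
  R <- max_value - min_value
  if (R == 0) {
    icz_warn("degenerate bounds (max == min): normalized value defined as 0",
             "icz_degenerate_bounds_warning")
    return(rep(0, length(value)))
  }
  a <- (value - min_value) / R
  if (any(a < 0 | a > 1)) {
    icz_warn(sprintf(
      "%d value(s) outside the repository bounds [%g, %g]; clamped to [0, 1]",
      sum(a < 0 | a > 1), min_value, max_value
    ), "icz_clamp_warning")
    a <- pmin(pmax(a, 0), 1)
  }
  a
}

FEATURE_KEYS <- c("f1", "f2", "f3", "f4", "d1")

#' Normalized five-feature vector
#'
#' @param f1,f2,f3,f4,d1 Dimensionless normalized values in `[0, 1]`.
#' @return A named numeric vector of class `"normalized_features"`.
#' @export
normalized_features <- function(f1, f2, f3, f4, d1) {
  v <- c(f1 = f1, f2 = f2, f3 = f3, f4 = f4, d1 = d1)
  if (!is.numeric(v) || length(v) != 5L || anyNA(v) || any(!is.finite(v))) {
    icz_validation_error("all five normalized values must be finite numbers")
  }
  if (any(v < 0 | v > 1)) {
    icz_validation_error("normalized values must lie in [0, 1]")
  }
  structure(v, class = "normalized_features")
}

#' @export
print.normalized_features <- function(x, ...) {
  cat("Normalized features:",
      paste(sprintf("%s = %.3f", names(unclass(x)), unclass(x)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Normalize a five-feature set against repository bounds
#'
#' @param x A [simplified_features()] object or a numeric vector of the five
#'   raw values in order F1, F2, F3, F4 (newtons), D1 (cm).
#' @param bounds An [compute_feature_bounds()] result.
#' @return A [normalized_features()] vector.
#' @export
normalize_features <- function(x, bounds) {
  if (!inherits(bounds, "icz_feature_bounds")) {
    icz_validation_error("bounds must come from compute_feature_bounds()")
  }
  raw <- if (inherits(x, "simplified_features")) {
    as.numeric(x)
  } else if (is.numeric(x) && length(x) == 5L) {
    as.vector(x)
  } else {
    icz_validation_error("x must be simplified_features or a numeric vector of length 5")
  }
  a <- vapply(seq_len(5L), function(i) {
    normalize_feature(raw[i], bounds$min_value[i], bounds$max_value[i])
  }, numeric(1))
  normalized_features(a[1L], a[2L], a[3L], a[4L], a[5L])
}

#' Per-feature similarity score
#'
#' The absolute difference of two normalized feature values: 0 means the
#' feature is identical in both subjects, 1 entirely different.
#'
#' @param a_b,a_u Normalized values in `[0, 1]` (vectors allowed).
#' @return `|a_b - a_u|`.
#' @export
feature_similarity <- function(a_b, a_u) {
  if (!is.numeric(a_b) || !is.numeric(a_u) || anyNA(a_b) || anyNA(a_u)) {
    icz_validation_error("inputs must be numeric without NA")
  }
  if (any(a_b < 0 | a_b > 1) || any(a_u < 0 | a_u > 1)) {
    icz_validation_error("inputs must lie in [0, 1]")
  }
  abs(a_b - a_u)
}

check_weights <- function(weights) {
  if (is.null(weights)) return(rep(1 / 5, 5L))
  if (!is.numeric(weights) || length(weights) != 5L || anyNA(weights) ||
      any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    icz_validation_error("weights must be five non-negative numbers summing to 1")
  }
  as.vector(weights)
}

#' Similarity statistic between two normalized feature vectors
#'
#' The dissimilarity score
#' `sim(x) = sum_i w_i * |a_ib - a_iu|`, by default the mean absolute
#' difference over the five normalized features (equal weights, as all
#' features are treated as equally important).  0 means the two subjects are
#' entirely similar, 1 entirely different.
#'
#' @param b,u [normalized_features()] vectors (repository entry and user).
#' @param weights Optional five non-negative weights summing to 1; default
#'   equal.
#' @return An object of class `"icz_similarity"`: list with `per_feature`
#'   (five named scores) and `total`.
#' @export
similarity <- function(b, u, weights = NULL) {
  w <- check_weights(weights)
  bv <- as_normalized(b)
  uv <- as_normalized(u)
  pf <- feature_similarity(bv, uv)
  names(pf) <- FEATURE_KEYS
  structure(
    list(per_feature = pf, total = sum(w * pf), weights = w),
    class = "icz_similarity"
  )
}

as_normalized <- function(x) {
  if (inherits(x, "normalized_features")) return(unclass(x))
  if (is.numeric(x) && length(x) == 5L) {
    return(unclass(normalized_features(x[1L], x[2L], x[3L], x[4L], x[5L])))
  }
  icz_validation_error("expected a normalized_features vector (or numeric length 5 in [0, 1])")
}

#' @export
print.icz_similarity <- function(x, ...) {
  cat(sprintf(
    "sim(x) = %.3f  [%s]\n", x$total,
    paste(sprintf("sim(%s) = %.3f", names(x$per_feature), x$per_feature),
          collapse = ", ")
  ))
  invisible(x)
}

#' Match a user's features against a repository
#'
#' Normalizes every repository row (and, if given in raw newtons/cm, the
#' user) against the repository's own feature bounds, scores each entry with
#' the [similarity()] statistic and ranks entries by ascending total (most
#' similar first).  Ties are broken by table order (first-listed entry wins).
#'
#' The user may be given either as raw measurements ([simplified_features()])
#' or as an already-normalized vector ([normalized_features()]); the latter
#' makes it possible to reproduce a worksheet whose normalized user row is
#' pinned.
#'
#' @param table An [feature_table()].
#' @param user A [simplified_features()] or [normalized_features()] object.
#' @param weights Optional five weights summing to 1; default equal.
#' @param threshold Optional acceptance threshold on the best total; if the
#'   best score exceeds it the match is flagged as not acceptable (the best
#'   entry is still reported).
#' @return An object of class `"icz_match"`: `results` (ranked data frame
#'   with `entry_id`, `sim_f1` ... `sim_d1`, `total`), `best_id`,
#'   `best_total`, `accepted` (`NA` when no threshold is given),
#'   `user_normalized`, `bounds`.
#' @examples
#' ws <- example_worksheet()
#' m <- match_features(ws$table, ws$user_normalized)
#' m$best_id       # "7"
#' @export
match_features <- function(table, user, weights = NULL, threshold = NULL) {
  table <- feature_table(table)
  w <- check_weights(weights)
  if (!is.null(threshold) && (!is_num(threshold) || threshold < 0)) {
    icz_validation_error("threshold must be a single non-negative number")
  }
  bounds <- compute_feature_bounds(table)

  u <- if (inherits(user, "normalized_features")) {
    unclass(user)
  } else if (inherits(user, "simplified_features")) {
    unclass(normalize_features(user, bounds))
  } else {
    icz_validation_error("user must be simplified_features or normalized_features")
  }

  cols <- c("F1_N", "F2_N", "F3_N", "F4_N", "D1_cm")
  rowsim <- t(vapply(seq_len(nrow(table)), function(i) {
    b <- vapply(seq_len(5L), function(j) {
      normalize_feature(table[[cols[j]]][i], bounds$min_value[j],
                        bounds$max_value[j])
    }, numeric(1))
    pf <- abs(b - u)
    c(pf, sum(w * pf))
  }, numeric(6)))

  results <- data.frame(
    entry_id = table$entry_id,
    sim_f1 = rowsim[, 1L], sim_f2 = rowsim[, 2L], sim_f3 = rowsim[, 3L],
    sim_f4 = rowsim[, 4L], sim_d1 = rowsim[, 5L],
    total = rowsim[, 6L],
    stringsAsFactors = FALSE
  )
  ord <- order(results$total, seq_len(nrow(results)))
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL

  best_total <- results$total[1L]
  structure(
    list(
      results = results,
      best_id = results$entry_id[1L],
      best_total = best_total,
      threshold = threshold,
      accepted = if (is.null(threshold)) NA else best_total <= threshold,
      user_normalized = u,
      weights = w,
      bounds = bounds
    ),
    class = "icz_match"
  )
}

#' @export
print.icz_match <- function(x, ...) {
  cat(sprintf("Best-matching repository entry: '%s' with sim(x) = %.3f\n",
              x$best_id, x$best_total))
  if (!is.null(x$threshold)) {
    cat(sprintf("Acceptance threshold %.3f: %s\n", x$threshold,
                if (isTRUE(x$accepted)) "acceptable match"
                else "no acceptable model in the repository"))
  }
  shown <- x$results
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], round, digits = 3L)
  print(utils::head(shown, 5L))
  if (nrow(x$results) > 5L) cat(sprintf("... and %d more entries\n",
                                        nrow(x$results) - 5L))
  invisible(x)
}

#' Write a match report as versioned JSON
#'
#' Mirrors the match result with both full-precision and 3-decimal display
#' fields.
#'
#' @param match An `"icz_match"` result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(match, path) {
  stopifnot(inherits(match, "icz_match"))
  disp <- match$results
  num <- vapply(disp, is.numeric, logical(1))
  disp[num] <- lapply(disp[num], round, digits = 3L)
  obj <- list(
    schema_version = 1L,
    best_id = match$best_id,
    best_total = match$best_total,
    best_total_display = round(match$best_total, 3L),
    threshold = match$threshold,
    accepted = match$accepted,
    weights = match$weights,
    user_normalized = as.list(match$user_normalized),
    results = match$results,
    results_display = disp
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
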