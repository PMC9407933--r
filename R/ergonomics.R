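#' Assess a single task point against a strength field
#'
#' A task point (e.g. a cupboard shelf position with the weight of the object
#' stored there) is checked for reachability and force adequacy: the
#' allowable force at the point is `F_d = k * F` with `F` the interpolated
#' limit force, and the verdict is
#' \describe{
#'   \item{`OK`}{the point is within reach and `F_d >=` the required force;}
#'   \item{`FORCE_INADEQUATE`}{within reach but `F_d <` required;}
#'   \item{`OUT_OF_REACH`}{beyond the reach boundary, or outside the modeled
#'     angular/height region (distinguished by the `note` field).  Available
#'     force is reported as 0.}
#' }
#'
#' @param field A `"strength_field"`.
#' @param point A list or one-row data frame with `alpha_deg`, `z_cm`,
#'   `r_cm`, `required_force_N` and optionally `label`.
#' @param fd_scale Proportional limit-to-allowable force correction
#'   `k` in `(0, 1]`.  Default 1.
#' @return A one-row data frame with columns `label`, `alpha_deg`, `z_cm`,
#'   `r_cm`, `required_force_N`, `available_force_N`, `margin_N`, `verdict`,
#'   `note`.
#' @export
assess_point <- function(field, point, fd_scale = 1) {
  stopifnot(inherits(field, "strength_field"))
  if (!is_num(fd_scale) || fd_scale <= 0 || fd_scale > 1) {
    icz_validation_error("fd_scale must be a single number in (0, 1]")
  }
  point <- as.list(point)
  for (nm in c("alpha_deg", "z_cm", "r_cm", "required_force_N")) {
    if (!is_num(point[[nm]] %||% NULL)) {
      icz_validation_error(sprintf("task point needs a numeric '%s'", nm))
    }
  }
  if (point$required_force_N < 0) {
    icz_validation_error("required_force_N must be >= 0")
  }
  if (point$r_cm < 0) icz_validation_error("r_cm must be >= 0")
  label <- point$label %||% ""

  if (!in_extent(point$alpha_deg, field$alpha_deg) ||
      !in_extent(point$z_cm, field$z_cm)) {
    available <- 0
    verdict <- "OUT_OF_REACH"
    note <- "outside modeled region"
  } else {
    reach <- reach_at(field, point$alpha_deg, point$z_cm)
    if (point$r_cm > reach + 1e-9) {
      available <- 0
      verdict <- "OUT_OF_REACH"
      note <- sprintf("beyond reach boundary (%.1f cm)", reach)
    } else {
      available <- fd_scale *
        field_value(field, point$alpha_deg, point$z_cm, point$r_cm)
      verdict <- if (available >= point$required_force_N) "OK"
                 else "FORCE_INADEQUATE"
      note <- ""
    }
  }
  data.frame(
    label = label,
    alpha_deg = point$alpha_deg, z_cm = point$z_cm, r_cm = point$r_cm,
    required_force_N = point$required_force_N,
    available_force_N = available,
    margin_N = available - point$required_force_N,
    verdict = verdict,
    note = note,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assess a product layout against a strength field
#'
#' Applies [assess_point()] to every task point, preserving order.
#'
#' @param field A `"strength_field"`.
#' @param layout Data frame of task points with columns `label`, `alpha_deg`,
#'   `z_cm`, `r_cm`, `required_force_N` (see [read_layout()]).  An empty
#'   layout yields an empty report.
#' @param fd_scale Limit-to-allowable correction in `(0, 1]`.
#' @return A data frame of class `"icz_layout_report"`, one row per task
#'   point.
#' @export
assess_layout <- function(field, layout, fd_scale = 1) {
  stopifnot(inherits(field, "strength_field"))
  if (!is.data.frame(layout)) {
    icz_validation_error("layout must be a data frame of task points")
  }
  if (nrow(layout) == 0L) {
    rep <- data.frame(
      label = character(), alpha_deg = numeric(), z_cm = numeric(),
      r_cm = numeric(), required_force_N = numeric(),
      available_force_N = numeric(), margin_N = numeric(),
      verdict = character(), note = character(), stringsAsFactors = FALSE
    )
    class(rep) <- c("icz_layout_report", "data.frame")
    return(rep)
  }
  if (!"label" %in% names(layout)) {
    layout$label <- sprintf("point-%d", seq_len(nrow(layout)))
  }
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    assess_point(field, layout[i, , drop = FALSE], fd_scale = fd_scale)
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  class(rep) <- c("icz_layout_report", "data.frame")
  rep
}

#' @export
print.icz_layout_report <- function(x, ...) {
  cat(sprintf("Layout assessment: %d point(s); %d OK, %d force-inadequate, %d out of reach\n",
              nrow(x), sum(x$verdict == "OK"),
              sum(x$verdict == "FORCE_INADEQUATE"),
              sum(x$verdict == "OUT_OF_REACH")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = 1L)
  print(y)
  invisible(x)
}

#' Read and write task layouts as CSV
#'
#' Format: comma-separated with header
#' `label,alpha_deg,z_cm,r_cm,required_force_N`; coordinates in the
#' body-centered cylindrical frame of the strength field.
#'
#' @param path CSV file path.
#' @param layout A data frame of task points.
#' @return `read_layout()` returns the validated data frame.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) {
    icz_schema_error(sprintf("layout file not found: %s", path))
  }
  need <- c("label", "alpha_deg", "z_cm", "r_cm", "required_force_N")
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8"),
    error = function(e) icz_schema_error(sprintf("cannot parse %s: %s",
                                                 path, conditionMessage(e)))
  )
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    icz_schema_error(sprintf("%s is missing column(s): %s",
                             path, paste(miss, collapse = ", ")))
  }
  raw <- raw[need]
  for (nm in need[-1L]) {
    num <- suppressWarnings(as.numeric(raw[[nm]]))
    if (anyNA(num) && nrow(raw) > 0L) {
      bad <- which(is.na(num))[1L]
      icz_schema_error(sprintf("%s: column %s, row %d: non-numeric value '%s'",
                               path, nm, bad, raw[[nm]][bad]))
    }
    raw[[nm]] <- num
  }
  raw
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  need <- c("label", "alpha_deg", "z_cm", "r_cm", "required_force_N")
  if (!is.data.frame(layout) || !all(need %in% names(layout))) {
    icz_validation_error(paste0("layout must have columns ",
                                paste(need, collapse = ", ")))
  }
  utils::write.csv(layout[need], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert room-frame Cartesian points to the body-centered frame
#'
#' The body frame assumes the person stands in one place: cylindrical
#' coordinates about the vertical body axis.  Given the body axis position on
#' the room floor and the facing direction, room Cartesian task points
#' (x, y in cm on the floor plan, z height) are converted to
#' `(alpha_deg, z_cm, r_cm)`.  In the body frame, `alpha = 0` points in the
#' facing direction and positive angles turn toward the measured limb's side.
#'
#' @param x,y,z Room coordinates in cm (vectors).
#' @param body_x,body_y Body axis position on the floor plan, cm.
#' @param facing_deg Facing direction in the room frame (0 = +y axis,
#'   measured clockwise toward +x).
#' @return Data frame with `alpha_deg`, `z_cm`, `r_cm`.
#' @export
body_frame_points <- function(x, y, z, body_x = 0, body_y = 0, facing_deg = 0) {
  dx <- x - body_x
  dy <- y - body_y
  alpha <- (atan2(dx, dy) * 180 / pi) - facing_deg
  alpha <- ((alpha + 180) %% 360) - 180
  data.frame(alpha_deg = alpha, z_cm = z, r_cm = sqrt(dx^2 + dy^2))
}
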