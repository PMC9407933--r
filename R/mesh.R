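#' Triangulate a constant-strength layer
#'
#' Converts the layer's `(alpha, z) -> r` boundary into a triangulated
#' surface in Cartesian coordinates (units cm, right-handed, z up; the
#' sagittal direction alpha = 0 maps to +y, positive alpha toward +x).
#'
#' @param layer A `"strength_layer"` with at least 2 angular and 2 height
#'   lattice lines.
#' @return An object of class `"icz_mesh"`: `vertices` (n x 3 matrix) and
#'   `faces` (m x 3 integer matrix, 1-based).
#' @export
layer_mesh <- function(layer) {
  stopifnot(inherits(layer, "strength_layer"))
  if (layer$empty) {
    icz_validation_error(sprintf(
      "layer at %g N is empty; no surface to triangulate", layer$level))
  }
  na <- length(layer$alpha_deg)
  nz <- length(layer$z_cm)
  if (na < 2L || nz < 2L) {
    icz_validation_error("layer needs at least 2 angular and 2 height lattice lines to triangulate")
  }
  rad <- layer$alpha_deg * pi / 180
  verts <- matrix(0, na * nz, 3L)
  vid <- function(ia, iz) (iz - 1L) * na + ia
  for (iz in seq_len(nz)) {
    r <- layer$boundary[, iz]
    verts[vid(seq_len(na), iz), ] <- cbind(r * sin(rad), r * cos(rad),
                                           layer$z_cm[iz])
  }
  faces <- matrix(0L, 2L * (na - 1L) * (nz - 1L), 3L)
  k <- 0L
  for (iz in seq_len(nz - 1L)) {
    for (ia in seq_len(na - 1L)) {
      v00 <- vid(ia, iz); v10 <- vid(ia + 1L, iz)
      v01 <- vid(ia, iz + 1L); v11 <- vid(ia + 1L, iz + 1L)
      faces[k + 1L, ] <- c(v00, v10, v11)
      faces[k + 2L, ] <- c(v00, v11, v01)
      k <- k + 2L
    }
  }
  structure(list(vertices = verts, faces = faces, level = layer$level),
            class = "icz_mesh")
}

#' @export
print.icz_mesh <- function(x, ...) {
  cat(sprintf("Mesh at %g N: %d vertices, %d triangles\n",
              x$level, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Write a mesh as ASCII OBJ or STL
#'
#' Units are cm, z up, right-handed.
#'
#' @param mesh An `"icz_mesh"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "icz_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# constant-strength layer surface (units cm, z up)", con)
  writeLines(sprintf("v %.6f %.6f %.6f",
                     mesh$vertices[, 1L], mesh$vertices[, 2L],
                     mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "icz_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid layer_%gN", mesh$level), con)
  for (i in seq_len(nrow(mesh$faces))) {
    p <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
    nrm <- c(
      (p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) - (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
      (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) - (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
      (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) - (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1])
    )
    len <- sqrt(sum(nrm^2))
    if (len > 0) nrm <- nrm / len else nrm <- c(0, 0, 1)
    writeLines(sprintf("  facet normal %.6f %.6f %.6f", nrm[1], nrm[2], nrm[3]), con)
    writeLines("    outer loop", con)
    writeLines(sprintf("      vertex %.6f %.6f %.6f", p[, 1], p[, 2], p[, 3]), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines(sprintf("endsolid layer_%gN", mesh$level), con)
  invisible(path)
}

#' Export constant-strength layers as mesh files
#'
#' Rescales the field by `fd_scale` (limit force to allowable force
#' `F_d = k * F`) and writes one mesh file per requested allowable-force
#' level.  Nesting is preserved: higher levels lie inside lower ones.
#'
#' @param field A `"strength_field"`.
#' @param levels Numeric vector of positive allowable-force levels (newtons).
#' @param dir Output directory (created if needed).
#' @param fd_scale Correction factor in `(0, 1]`.  Default 1.
#' @param format `"obj"` or `"stl"`.
#' @return Character vector of written file paths, invisibly.  Empty layers
#'   (level above the field maximum) are skipped with a warning.
#' @export
export_layers <- function(field, levels, dir, fd_scale = 1, format = c("obj", "stl")) {
  format <- match.arg(format)
  stopifnot(inherits(field, "strength_field"))
  if (!is.numeric(levels) || length(levels) == 0L || any(levels <= 0)) {
    icz_validation_error("levels must be positive forces in newtons")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rescaled <- rescale_forces(field, fd_scale)
  writer <- if (format == "obj") write_obj else write_stl
  paths <- character(0)
  for (lv in levels) {
    layer <- extract_constant_strength_layer(rescaled, lv)
    if (layer$empty) {
      icz_warn(sprintf("layer at %g N is empty (above the field maximum); skipped", lv),
               "icz_empty_layer_warning")
      next
    }
    path <- file.path(dir, sprintf("layer_%gN.%s", lv, format))
    writer(layer_mesh(layer), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
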