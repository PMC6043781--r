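# Volumetric containers, NIfTI I/O, affine coordinate transforms and
# nearest-neighbour resampling shared by the whole pipeline.

VOLUME_KINDS <- c("atlas", "tissue", "mask", "statmap")

#' Construct a 3D volume with a voxel-to-world affine
#'
#' A `volume3d` couples a 3D scalar array with a 4x4 affine mapping 0-based
#' voxel indices (voxel centers, NIfTI convention) to world coordinates in mm
#' (RAS-oriented). The `kind` declares the value semantics and is validated:
#' `"mask"` volumes are binary, `"tissue"` volumes use 0 = background,
#' 1 = CSF, 2 = gray matter, 3 = white matter, `"atlas"` volumes hold
#' non-negative integer parcel labels with 0 meaning unlabeled, and
#' `"statmap"` volumes hold arbitrary floats (NaN allowed).
#'
#' @param data Numeric 3D array.
#' @param affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#' @param kind One of `"atlas"`, `"tissue"`, `"mask"`, `"statmap"`.
#' @return An object of class `volume3d` with fields `data`, `affine`, `kind`.
#' @export
volume3d <- function(data, affine, kind) {
  kind <- match.arg(kind, VOLUME_KINDS)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume3d: `data` must be a 3D array, got ",
         paste(dim(data), collapse = "x"), call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("volume3d: `affine` must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) <= .Machine$double.eps)
    stop("volume3d: affine 3x3 part is singular", call. = FALSE)
  validate_volume_values(data, kind)
  structure(list(data = data, affine = affine, kind = kind),
            class = "volume3d")
}

validate_volume_values <- function(data, kind) {
  v <- as.vector(data)
  if (kind == "mask") {
    bad <- v[!(v %in% c(0, 1))]
    if (length(bad))
      stop(sprintf("mask volume contains out-of-range value %g (allowed: 0, 1)",
                   bad[1L]), call. = FALSE)
  } else if (kind == "tissue") {
    bad <- v[!(v %in% 0:3)]
    if (length(bad))
      stop(sprintf(
        "tissue volume contains out-of-range value %g (allowed: 0=background, 1=CSF, 2=GM, 3=WM)",
        bad[1L]), call. = FALSE)
  } else if (kind == "atlas") {
    bad <- v[v < 0 | v != round(v)]
    if (length(bad))
      stop(sprintf(
        "atlas volume contains invalid label %g (labels are non-negative integers)",
        bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d kind=%s dim=%s voxel=%.3gx%.3gx%.3g mm>\n",
              x$kind, paste(dim(x$data), collapse = "x"),
              sqrt(sum(x$affine[1:3, 1]^2)), sqrt(sum(x$affine[1:3, 2]^2)),
              sqrt(sum(x$affine[1:3, 3]^2))))
  invisible(x)
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads a single-frame NIfTI-1 image and validates its values against the
#' declared `kind` (see [volume3d()]). The affine is taken from the header's
#' voxel-to-world mapping (sform preferred).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind Volume kind; see [volume3d()].
#' @return A `volume3d`.
#' @export
read_volume <- function(path, kind) {
  if (!file.exists(path))
    stop("read_volume: file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img_data <- array(as.vector(as.array(img)), dim = d[1:3])
  } else if (length(d) != 3L) {
    stop(sprintf("read_volume: expected a 3D volume, got %d dimensions (%s)",
                 length(d), paste(d, collapse = "x")), call. = FALSE)
  } else {
    img_data <- array(as.vector(as.array(img)), dim = d)
  }
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume3d(img_data, aff, kind)
}

#' Write a volume to NIfTI-1
#'
#' The affine is stored in the sform (and qform) so that write followed by
#' read is the identity on data and affine up to float32 representation.
#'
#' @param vol A `volume3d`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  dat <- vol$data
  if (vol$kind %in% c("atlas", "tissue", "mask")) {
    img <- RNifti::asNifti(array(as.integer(dat), dim = dim(dat)),
                           datatype = "int32")
  } else {
    img <- RNifti::asNifti(dat, datatype = "double")
  }
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Map voxel indices to world coordinates
#'
#' Voxel indices are 0-based and may be fractional; the affine maps voxel
#' centers to world mm.
#'
#' @param v Length-3 vector or n x 3 matrix of 0-based voxel indices.
#' @param vol A `volume3d`, or a 4x4 affine matrix.
#' @return World coordinates, same shape as `v`.
#' @export
voxel_to_world <- function(v, vol) {
  aff <- if (inherits(vol, "volume3d")) vol$affine else as.matrix(vol)
  pts <- if (is.matrix(v)) v else matrix(v, ncol = 3L)
  out <- cbind(pts, 1) %*% t(aff)
  out <- out[, 1:3, drop = FALSE]
  if (is.matrix(v)) out else drop(out)
}

#' Map world coordinates to (fractional) voxel indices
#'
#' Exact inverse of [voxel_to_world()].
#'
#' @inheritParams voxel_to_world
#' @param w Length-3 vector or n x 3 matrix of world mm coordinates.
#' @export
world_to_voxel <- function(w, vol) {
  aff <- if (inherits(vol, "volume3d")) vol$affine else as.matrix(vol)
  voxel_to_world(w, solve(aff))
}

#' Construct and validate a rigid world-to-world transform
#'
#' @param matrix 4x4 numeric matrix; the 3x3 part must be a proper rotation
#'   (orthonormal, determinant +1) within `tol`.
#' @param tol Orthonormality tolerance (default 1e-6).
#' @return A `rigid_transform` object (a classed 4x4 matrix).
#' @export
rigid_transform <- function(matrix, tol = 1e-6) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(4L, 4L)))
    stop("rigid_transform: expected a 4x4 matrix", call. = FALSE)
  R <- m[1:3, 1:3]
  if (max(abs(t(R) %*% R - diag(3))) > tol)
    stop("rigid_transform: 3x3 part is not orthonormal (tolerance ", tol, ")",
         call. = FALSE)
  if (det(R) < 0)
    stop("rigid_transform: 3x3 part has negative determinant (reflection)",
         call. = FALSE)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > tol)
    stop("rigid_transform: last row must be (0,0,0,1)", call. = FALSE)
  m[4, ] <- c(0, 0, 0, 1)
  structure(m, class = "rigid_transform")
}

#' Identity rigid transform
#' @export
identity_transform <- function() rigid_transform(diag(4))

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @export
invert_transform <- function(t) rigid_transform(solve(unclass(t)))

#' Apply a rigid transform to world points
#' @param t A `rigid_transform`.
#' @param pts Length-3 vector or n x 3 matrix of world mm points.
#' @export
apply_transform <- function(t, pts) voxel_to_world(pts, unclass(t))

#' Read a 4x4 transform from a plain-text file
#'
#' The file holds one matrix row per line (whitespace-separated); lines
#' starting with `#` are comments. By convention the matrix maps target world
#' space to source world space (stated in the file header when written by
#' [write_transform()]).
#'
#' @param path File path.
#' @return A `rigid_transform`.
#' @export
read_transform <- function(path) {
  if (!file.exists(path))
    stop("read_transform: file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) != 4L)
    stop("read_transform: expected 4 matrix rows, got ", length(lines),
         call. = FALSE)
  m <- t(vapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]]), numeric(4L)))
  dimnames(m) <- NULL
  rigid_transform(m)
}

#' Write a 4x4 transform to a plain-text file
#' @param t A `rigid_transform`.
#' @param path Output path.
#' @export
write_transform <- function(t, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rigid transform: target world mm -> source world mm", con)
  writeLines(apply(unclass(t), 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  invisible(path)
}

#' Resample a volume onto a target grid by nearest neighbour
#'
#' Each target voxel center is mapped to world space with the target affine,
#' moved into the source world space with the rigid transform `t`
#' (target world -> source world), converted to a source voxel index, and
#' assigned the value of the nearest source voxel. Voxels mapping outside the
#' source grid are set to 0 (background / unlabeled), never clamped to the
#' nearest edge.
#'
#' @param src Source `volume3d`.
#' @param target_grid `volume3d` supplying the output shape and affine.
#' @param t `rigid_transform` mapping target world space to source world
#'   space; defaults to the identity.
#' @return A `volume3d` with the target's shape and affine and the source's
#'   `kind`.
#' @export
resample_nearest <- function(src, target_grid, t = identity_transform()) {
  stopifnot(inherits(src, "volume3d"), inherits(target_grid, "volume3d"))
  if (!inherits(t, "rigid_transform")) t <- rigid_transform(t)
  dt <- dim(target_grid$data)
  ds <- dim(src$data)
  # all 0-based target voxel indices
  idx <- as.matrix(expand.grid(i = 0:(dt[1] - 1), j = 0:(dt[2] - 1),
                               k = 0:(dt[3] - 1)))
  # compose: target voxel -> target world -> src world -> src voxel
  M <- solve(src$affine) %*% unclass(t) %*% target_grid$affine
  sv <- round(cbind(idx, 1) %*% t(M))[, 1:3, drop = FALSE]
  inb <- sv[, 1] >= 0 & sv[, 1] < ds[1] &
         sv[, 2] >= 0 & sv[, 2] < ds[2] &
         sv[, 3] >= 0 & sv[, 3] < ds[3]
  out <- numeric(nrow(idx))
  lin <- sv[inb, 1] + ds[1] * (sv[inb, 2] + ds[2] * sv[inb, 3]) + 1
  out[inb] <- src$data[lin]
  storage.mode(out) <- storage.mode(src$data)
  volume3d(array(out, dim = dt), target_grid$affine, src$kind)
}

#' Read a label lookup table
#'
#' Tab-separated file with header columns `label`, `name`, `hemisphere`
#' (`L`, `R` or `none`) and `atlas`; an optional logical `cortical` column (or
#' the `cortical` argument) marks the atlas as cortical, in which case contact
#' labeling restricts candidate voxels to gray matter.
#'
#' @param path TSV file path.
#' @param cortical Overrides/sets the cortical flag for the whole atlas.
#' @return A `label_lookup`: a data.frame with attributes `atlas_name` and
#'   `cortical`.
#' @export
read_label_lookup <- function(path, cortical = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("label", "name", "hemisphere", "atlas")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_label_lookup: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(cortical))
    cortical <- if ("cortical" %in% names(df)) isTRUE(as.logical(df$cortical[1L])) else FALSE
  label_lookup(df[need], atlas_name = df$atlas[1L], cortical = cortical)
}

#' Construct a label lookup table
#'
#' @param entries data.frame with columns `label`, `name`, `hemisphere`,
#'   `atlas`.
#' @param atlas_name Atlas identifier.
#' @param cortical Whether contact labeling against this atlas should consider
#'   gray-matter voxels only.
#' @export
label_lookup <- function(entries, atlas_name = entries$atlas[1L],
                         cortical = FALSE) {
  stopifnot(is.data.frame(entries))
  entries$label <- as.integer(entries$label)
  if (any(entries$label == 0L))
    stop("label_lookup: label 0 is reserved for 'unlabeled'", call. = FALSE)
  if (anyDuplicated(entries$label))
    stop("label_lookup: duplicate label ids", call. = FALSE)
  if (anyDuplicated(entries$name))
    stop("label_lookup: parcel names must be unique within an atlas",
         call. = FALSE)
  if (!all(entries$hemisphere %in% c("L", "R", "none")))
    stop("label_lookup: hemisphere must be one of L, R, none", call. = FALSE)
  structure(entries[c("label", "name", "hemisphere", "atlas")],
            atlas_name = atlas_name, cortical = isTRUE(cortical),
            class = c("label_lookup", "data.frame"))
}

#' Write a label lookup table to TSV
#' @param lookup A `label_lookup`.
#' @param path Output path.
#' @export
write_label_lookup <- function(lookup, path) {
  df <- as.data.frame(lookup)
  df$cortical <- attr(lookup, "cortical")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

lookup_name <- function(lookup, label) {
  if (label == 0L) return("unlabeled")
  i <- match(label, lookup$label)
  if (is.na(i))
    stop(sprintf("label %d not present in lookup for atlas '%s'",
                 label, attr(lookup, "atlas_name")), call. = FALSE)
  lookup$name[i]
}

#' Do two volumes share the same grid?
#'
#' Same array dimensions and affines equal within `tol`.
#' @param a,b `volume3d` objects.
#' @param tol Elementwise affine tolerance.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}

#' Voxel volume in mm^3
#' @param vol A `volume3d`.
#' @export
voxel_volume <- function(vol) abs(det(vol$affine[1:3, 1:3]))
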