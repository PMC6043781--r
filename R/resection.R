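# Resection-mask computation from pre/post-operative brain masks:
# difference, morphological opening, seeded connected-component selection,
# volume and per-parcel overlap quantification.
#
# The binary morphology and component labeling operate on small 3D arrays
# and are implemented directly with array shifts (no 3D morphology package
# is required by the rest of the pipeline).

# shift a 3D array by integer offsets, zero-filling
shift3d <- function(a, off) {
  d <- dim(a)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o) }
    else { dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

neighbor_offsets <- function(connectivity = 26L) {
  offs <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  manh <- rowSums(abs(offs))
  switch(as.character(connectivity),
         "6" = offs[manh == 1, , drop = FALSE],
         "18" = offs[manh <= 2, , drop = FALSE],
         "26" = offs,
         stop("connectivity must be 6, 18 or 26", call. = FALSE))
}

# binary erosion/dilation by the 6-connected cross (radius 1), `iter` times
erode_cross <- function(a, iter = 1L) {
  for (i in seq_len(iter)) {
    acc <- a
    for (r in seq_len(6)) {
      off <- neighbor_offsets(6L)[r, ]
      acc <- acc * shift3d(a, off)
    }
    a <- acc
  }
  a
}

dilate_cross <- function(a, iter = 1L) {
  for (i in seq_len(iter)) {
    acc <- a
    for (r in seq_len(6)) {
      off <- neighbor_offsets(6L)[r, ]
      acc <- pmax(acc, shift3d(a, off))
    }
    a <- acc
  }
  a
}

#' Morphological opening of a binary 3D array
#'
#' Erosion followed by dilation with a 6-connected cross structuring element
#' of radius 1 voxel, repeated `iter` times each.
#'
#' @param a Binary 3D array (0/1).
#' @param iter Iterations (default 1).
#' @return Binary 3D array.
#' @export
binary_opening <- function(a, iter = 1L) dilate_cross(erode_cross(a, iter), iter)

#' Connected-component labeling of a binary 3D array
#'
#' Iterative minimum-label propagation until convergence.
#'
#' @param a Binary 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array: 0 for background, components numbered 1..n in order
#'   of their first (lexicographically smallest) voxel.
#' @export
connected_components <- function(a, connectivity = 26L) {
  d <- dim(a)
  offs <- neighbor_offsets(connectivity)
  mask <- a != 0
  lab <- array(seq_len(prod(d)), dim = d)
  lab[!mask] <- Inf
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      sh <- shift3d_inf(lab, offs[r, ])
      new <- pmin(new, sh)
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- array(0L, dim = d)
  ids <- sort(unique(lab[mask]))
  out[mask] <- match(lab[mask], ids)
  out
}

# like shift3d but Inf-filled (for min-propagation)
shift3d_inf <- function(a, off) {
  d <- dim(a)
  out <- array(Inf, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o) }
    else { dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Compute the resection mask from pre- and post-operative brain masks
#'
#' Pipeline: (1) the post-operative brain mask is resampled onto the
#' pre-implantation grid with the rigid transform `t` (nearest neighbour;
#' the mask is binary); (2) the difference keeps every voxel present in the
#' pre-implantation mask but absent post-operatively; (3) one morphological
#' opening (cross element, radius 1) smooths away misregistration fringe;
#' (4) connected components are labeled; (5) only the component containing
#' the voxel nearest the user-provided seed is kept. The result is
#' qualitative: it ignores post-surgical brain deformation, so downstream
#' overlap percentages carry a `brain_shift_unreliable` flag.
#'
#' @param pre_mask Pre-implantation brain mask (`volume3d`, kind mask),
#'   defining the output grid.
#' @param post_mask Post-resection brain mask (any grid).
#' @param t `rigid_transform` mapping pre-implantation world space to
#'   post-operative world space; identity by default.
#' @param seed Length-3 world mm point inside the resection cavity.
#' @param opening_iter Opening iterations (default 1).
#' @param connectivity Component connectivity, 6/18/26 (default 26).
#' @return A `resection_mask`: list with `mask` (`volume3d`) and
#'   `seed_point`.
#' @export
compute_resection <- function(pre_mask, post_mask, t = identity_transform(),
                              seed, opening_iter = 1L, connectivity = 26L) {
  stopifnot(inherits(pre_mask, "volume3d"), inherits(post_mask, "volume3d"))
  post_res <- resample_nearest(post_mask, pre_mask, t)
  diffm <- (pre_mask$data == 1) & (post_res$data != 1)
  if (!any(diffm))
    stop("no resection detected (pre- and post-operative masks are identical after resampling)",
         call. = FALSE)
  opened <- binary_opening(array(as.numeric(diffm), dim = dim(diffm)),
                           iter = opening_iter)
  comp <- connected_components(opened, connectivity)
  sv <- round(world_to_voxel(as.numeric(seed), pre_mask))
  d <- dim(pre_mask$data)
  if (any(sv < 0) || any(sv >= d))
    stop("compute_resection: seed point lies outside the volume", call. = FALSE)
  cid <- comp[sv[1] + 1, sv[2] + 1, sv[3] + 1]
  if (cid == 0L) {
    sizes <- tabulate(comp[comp > 0])
    stop(sprintf(
      "compute_resection: seed voxel is not inside any component (%d component(s), sizes: %s)",
      length(sizes), paste(sizes, collapse = ", ")), call. = FALSE)
  }
  keep <- array(as.numeric(comp == cid), dim = d)
  structure(list(mask = volume3d(keep, pre_mask$affine, "mask"),
                 seed_point = as.numeric(seed)),
            class = "resection_mask")
}

#' Volume of a resection mask in mm^3
#'
#' Voxel count times the voxel volume (|det| of the affine 3x3 part).
#'
#' @param r A `resection_mask` or a binary `volume3d`.
#' @export
resection_volume <- function(r) {
  vol <- if (inherits(r, "resection_mask")) r$mask else r
  sum(vol$data == 1) * voxel_volume(vol)
}

#' Per-parcel overlap of a resection with an atlas
#'
#' For every nonzero parcel, the percentage of the parcel's volume removed by
#' the resection: `100 * |parcel voxels inside mask| / |parcel voxels|`.
#' Parcels with no overlap are omitted. The report carries
#' `brain_shift_unreliable = TRUE`: the estimate ignores post-surgical brain
#' deformation and is qualitative.
#'
#' @param r A `resection_mask` (or binary `volume3d` on the atlas grid).
#' @param atlas `volume3d` of kind atlas on the pre-implantation grid.
#' @param lookup `label_lookup` for the atlas.
#' @return An `overlap_report`: list with `total_volume_mm3`, `per_parcel`
#'   (data.frame: atlas, label, name, parcel_voxels, resected_voxels,
#'   percent), `brain_shift_unreliable`.
#' @export
parcel_overlap <- function(r, atlas, lookup) {
  mask <- if (inherits(r, "resection_mask")) r$mask else r
  if (!same_grid(mask, atlas))
    stop("parcel_overlap: resection mask and atlas are not on the same grid",
         call. = FALSE)
  labs <- as.vector(atlas$data)
  inmask <- as.vector(mask$data) == 1
  tot <- table(labs[labs != 0])
  hit <- table(labs[labs != 0 & inmask])
  per <- data.frame(
    atlas = rep(attr(lookup, "atlas_name"), length(hit)),
    label = as.integer(names(hit)),
    name = vapply(as.integer(names(hit)), lookup_name, "", lookup = lookup),
    parcel_voxels = as.integer(tot[names(hit)]),
    resected_voxels = as.integer(hit),
    stringsAsFactors = FALSE)
  per$percent <- 100 * per$resected_voxels / per$parcel_voxels
  per <- per[order(per$label), , drop = FALSE]
  rownames(per) <- NULL
  structure(list(total_volume_mm3 = resection_volume(mask),
                 per_parcel = per, brain_shift_unreliable = TRUE),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report: %.1f mm^3 resected, %d parcel(s) affected%s>\n",
              x$total_volume_mm3, nrow(x$per_parcel),
              if (isTRUE(x$brain_shift_unreliable))
                "; caveat: sensitive to post-surgical brain shift" else ""))
  if (nrow(x$per_parcel)) print(x$per_parcel, ...)
  invisible(x)
}

#' Write an overlap report as JSON + CSV
#' @param report An `overlap_report`.
#' @param json_path Path for the JSON report (or NULL to skip).
#' @param csv_path Path for the per-parcel CSV table (or NULL to skip).
#' @export
write_overlap_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(
      list(total_volume_mm3 = report$total_volume_mm3,
           brain_shift_unreliable = report$brain_shift_unreliable,
           per_parcel = report$per_parcel),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(report$per_parcel, csv_path, row.names = FALSE)
  invisible(report)
}
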