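# Per-contact anatomical labeling: sphere neighbourhoods around contact
# centers in the pre-implantation grid, majority vote over atlas parcels
# (gray-matter restricted for cortical atlases), tissue class, statistical-map
# means and resection membership.

TISSUE_CSF <- 1L
TISSUE_GM <- 2L
TISSUE_WM <- 3L

#' Voxels whose centers fall inside a sphere
#'
#' Returns the 0-based indices of exactly the in-bounds voxels whose
#' world-space centers lie at Euclidean distance `<= radius_mm` from
#' `center`, in deterministic lexicographic order (sorted by i, then j, then
#' k). Membership uses voxel centers, not partial volumes, so a brute-force
#' per-voxel distance count is an exact oracle.
#'
#' @param center Length-3 world mm point.
#' @param vol A `volume3d` defining the grid.
#' @param radius_mm Sphere radius in mm (default 3, the atlas/tissue labeling
#'   radius); must be positive and at most 20.
#' @return Integer matrix (n x 3) of 0-based voxel indices; zero rows if the
#'   sphere lies entirely outside the volume.
#' @export
sphere_voxels <- function(center, vol, radius_mm = 3) {
  stopifnot(inherits(vol, "volume3d"))
  if (!is.finite(radius_mm) || radius_mm <= 0 || radius_mm > 20)
    stop("sphere_voxels: radius_mm must be in (0, 20]", call. = FALSE)
  d <- dim(vol$data)
  inv <- solve(vol$affine)
  cv <- voxel_to_world(as.numeric(center), inv)  # fractional voxel coords
  # conservative per-axis half-extent in voxel units: radius times the norm
  # of the corresponding row of the inverse 3x3 affine
  half <- radius_mm * sqrt(rowSums(inv[1:3, 1:3]^2))
  lo <- pmax(ceiling(cv - half), 0)
  hi <- pmin(floor(cv + half), d - 1)
  if (any(lo > hi)) return(matrix(integer(0), ncol = 3L,
                                  dimnames = list(NULL, c("i", "j", "k"))))
  cand <- as.matrix(expand.grid(k = lo[3]:hi[3], j = lo[2]:hi[2],
                                i = lo[1]:hi[1]))[, 3:1, drop = FALSE]
  w <- voxel_to_world(cand, vol)
  keep <- rowSums(sweep(w, 2L, as.numeric(center))^2) <= radius_mm^2 + 1e-12
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
  storage.mode(out) <- "integer"
  colnames(out) <- c("i", "j", "k")
  out
}

# values of vol at 0-based index matrix
voxel_values <- function(vol, idx) {
  d <- dim(vol$data)
  vol$data[idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3]) + 1]
}

# modal value with smallest-value tie-break; x non-empty
modal_smallest <- function(x) {
  tab <- table(x)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}

#' Atlas label of a contact by sphere majority vote
#'
#' The most common parcel label among the sphere's voxels is assigned to the
#' contact. For a cortical atlas (the lookup's `cortical` flag) with a tissue
#' volume available, candidate voxels are restricted to gray matter with a
#' nonzero atlas label: even if most of the sphere lies in white matter, the
#' contact still receives a cortical label when some gray-matter parcel
#' voxels fall inside the sphere. Without tissue information the vote runs
#' over all nonzero-label voxels. An empty candidate set yields
#' `(0, "unlabeled")`. Exact ties are broken toward the smallest label id
#' (determinism).
#'
#' @param center Length-3 world mm contact center.
#' @param atlas `volume3d` of kind `"atlas"`.
#' @param lookup `label_lookup` for the atlas.
#' @param tissue Optional `volume3d` of kind `"tissue"` on the same grid.
#' @param radius_mm Sphere radius (default 3 mm).
#' @return List with `label` (integer) and `name`.
#' @export
label_atlas <- function(center, atlas, lookup, tissue = NULL, radius_mm = 3) {
  stopifnot(inherits(atlas, "volume3d"))
  if (!is.null(tissue) && !same_grid(atlas, tissue))
    stop("label_atlas: atlas and tissue volumes are not on the same grid",
         call. = FALSE)
  idx <- sphere_voxels(center, atlas, radius_mm)
  if (nrow(idx) == 0L) return(list(label = 0L, name = "unlabeled"))
  labs <- voxel_values(atlas, idx)
  keep <- labs != 0
  if (!is.null(tissue) && attr(lookup, "cortical"))
    keep <- keep & (voxel_values(tissue, idx) == TISSUE_GM)
  labs <- labs[keep]
  if (!length(labs)) return(list(label = 0L, name = "unlabeled"))
  lab <- as.integer(modal_smallest(labs))
  list(label = lab, name = lookup_name(lookup, lab))
}

#' Tissue class of a contact by sphere majority vote
#'
#' Modal tissue class over in-sphere voxels with nonzero tissue value;
#' `"unlabeled"` if the sphere holds only background. Exact ties are broken
#' by the fixed priority GM > WM > CSF.
#'
#' @inheritParams label_atlas
#' @param tissue `volume3d` of kind `"tissue"`.
#' @return One of `"GM"`, `"WM"`, `"CSF"`, `"unlabeled"`.
#' @export
label_tissue <- function(center, tissue, radius_mm = 3) {
  stopifnot(inherits(tissue, "volume3d"))
  idx <- sphere_voxels(center, tissue, radius_mm)
  if (nrow(idx) == 0L) return("unlabeled")
  v <- voxel_values(tissue, idx)
  v <- v[v != 0]
  if (!length(v)) return("unlabeled")
  counts <- c(GM = sum(v == TISSUE_GM), WM = sum(v == TISSUE_WM),
              CSF = sum(v == TISSUE_CSF))
  names(counts)[which.max(counts)]  # which.max keeps GM > WM > CSF on ties
}

#' Mean of a statistical map around a contact
#'
#' Arithmetic mean of the in-sphere voxel values, excluding NaN voxels.
#' The default radius is 1.5 mm (a 3 mm diameter sphere), the conventional
#' choice for statistical maps, distinct from the 3 mm labeling radius.
#'
#' @inheritParams label_atlas
#' @param stat `volume3d` of kind `"statmap"`.
#' @param radius_mm Sphere radius (default 1.5 mm).
#' @return Mean value, or `NaN` (with a warning) for an empty sphere.
#' @export
statmap_mean <- function(center, stat, radius_mm = 1.5) {
  stopifnot(inherits(stat, "volume3d"))
  idx <- sphere_voxels(center, stat, radius_mm)
  v <- if (nrow(idx)) voxel_values(stat, idx) else numeric(0)
  v <- v[!is.nan(v)]
  if (!length(v)) {
    warning("statmap_mean: empty sphere at (",
            paste(signif(center, 4), collapse = ", "), "); returning NaN")
    return(NaN)
  }
  mean(v)
}

#' Is a contact inside the resection mask?
#'
#' True iff the voxel containing `center` (nearest voxel center) has mask
#' value 1; positions outside the volume are outside the resection.
#'
#' @param center Length-3 world mm contact center.
#' @param resection `volume3d` of kind `"mask"` on the pre-implantation grid.
#' @return Logical.
#' @export
resection_flag <- function(center, resection) {
  stopifnot(inherits(resection, "volume3d"))
  v <- round(world_to_voxel(as.numeric(center), resection))
  d <- dim(resection$data)
  if (any(v < 0) || any(v >= d)) return(FALSE)
  resection$data[v[1] + 1, v[2] + 1, v[3] + 1] == 1
}

#' Label every contact of an implantation
#'
#' Produces one row per contact with its parcel label in every atlas, tissue
#' class, per-statmap sphere means and resection membership. All volumes must
#' share the pre-implantation grid (resample first otherwise). Rows are
#' ordered by electrode name then contact index, so reruns on identical
#' inputs are byte-identical.
#'
#' @param electrodes List of `placed_electrode` objects (unique names).
#' @param atlases Named list; each element a list with fields `volume`
#'   (`volume3d`, kind atlas) and `lookup` (`label_lookup`).
#' @param tissue Optional tissue `volume3d`.
#' @param resection Optional resection mask `volume3d`.
#' @param statmaps Named list of statmap `volume3d`s.
#' @param label_radius_mm Sphere radius for atlas/tissue labels (default 3).
#' @param statmap_radius_mm Sphere radius for statmap means (default 1.5).
#' @return data.frame with columns `electrode`, `contact`, `x`, `y`, `z`,
#'   one `<atlas>_label` / `<atlas>_name` pair per atlas, `tissue`,
#'   `in_resection`, and one `stat_<name>` column per statmap.
#' @export
label_all <- function(electrodes, atlases = list(), tissue = NULL,
                      resection = NULL, statmaps = list(),
                      label_radius_mm = 3, statmap_radius_mm = 1.5) {
  nms <- vapply(electrodes, `[[`, "", "electrode_name")
  if (anyDuplicated(nms))
    stop("label_all: duplicate electrode names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  grids <- c(lapply(atlases, `[[`, "volume"),
             if (!is.null(tissue)) list(tissue),
             if (!is.null(resection)) list(resection), statmaps)
  if (length(grids) > 1L)
    for (g in grids[-1L]) if (!same_grid(grids[[1L]], g))
      stop("label_all: all volumes must share the pre-implantation grid",
           call. = FALSE)

  electrodes <- electrodes[order(nms)]
  rows <- list()
  for (el in electrodes) {
    centers <- el$contact_centers
    for (ci in seq_len(nrow(centers))) {
      ctr <- centers[ci, ]
      row <- list(electrode = el$electrode_name, contact = ci,
                  x = unname(ctr[1]), y = unname(ctr[2]), z = unname(ctr[3]))
      for (an in names(atlases)) {
        la <- label_atlas(ctr, atlases[[an]]$volume, atlases[[an]]$lookup,
                          tissue = tissue, radius_mm = label_radius_mm)
        row[[paste0(an, "_label")]] <- la$label
        row[[paste0(an, "_name")]] <- la$name
      }
      row$tissue <- if (!is.null(tissue))
        label_tissue(ctr, tissue, radius_mm = label_radius_mm) else NA_character_
      row$in_resection <- if (!is.null(resection))
        resection_flag(ctr, resection) else NA
      for (sn in names(statmaps))
        row[[paste0("stat_", sn)]] <-
          suppressWarnings(statmap_mean(ctr, statmaps[[sn]],
                                        radius_mm = statmap_radius_mm))
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write a contact-label table to CSV
#' @param labels data.frame from [label_all()].
#' @param path Output path.
#' @export
write_contact_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
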