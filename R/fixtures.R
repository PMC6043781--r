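# Deterministic synthetic fixtures: heads, atlases, implantations, post-op
# masks and whole cohorts, so the full pipeline runs and is testable with
# zero clinical data. Every output is a pure function of the spec (seed
# included).

#' Specification of a synthetic fixture set
#'
#' Defaults emulate a typical SEEG exploration: a 64 mm cube head at 1 mm
#' isotropic resolution, 16 gray-matter parcels (8 per hemisphere, sized
#' like real cortical parcels), 12 depth electrodes of 15 contacts each
#' (~180 contacts), and a 20-patient cohort
#' with 10% planted QC outliers whose MNI coordinates are displaced by 40 mm
#' on every axis against a 2 mm normalization jitter.
#'
#' @param grid_shape Integer length-3 grid dimensions (each >= 16).
#' @param voxel_size_mm Length-3 voxel spacing.
#' @param seed Integer; fully determines every generated output.
#' @param n_parcels Even number of atlas parcels (L/R pairs).
#' @param n_electrodes Electrodes per implantation.
#' @param n_contacts Contacts per electrode.
#' @param resection_corner 0-based voxel corner of the resection block.
#' @param resection_size Length-3 block size in voxels.
#' @param n_patients Cohort size.
#' @param outlier_rate Fraction of patients planted as QC outliers.
#' @param jitter_sd_mm MNI normalization jitter (Gaussian sd per axis).
#' @param outlier_shift_mm Per-axis MNI displacement of planted outliers.
#' @export
fixture_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size_mm = c(1, 1, 1), seed = 1L,
                         n_parcels = 16L, n_electrodes = 12L,
                         n_contacts = 15L,
                         resection_corner = c(48L, 30L, 30L),
                         resection_size = c(5L, 5L, 5L),
                         n_patients = 20L, outlier_rate = 0.1,
                         jitter_sd_mm = 2, outlier_shift_mm = 40) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L),
            all(voxel_size_mm > 0), n_parcels >= 2L, n_parcels %% 2L == 0L,
            n_electrodes >= 1L, n_contacts >= 1L,
            outlier_rate >= 0, outlier_rate <= 1)
  list(grid_shape = as.integer(grid_shape),
       voxel_size_mm = as.numeric(voxel_size_mm), seed = as.integer(seed),
       n_parcels = as.integer(n_parcels),
       n_electrodes = as.integer(n_electrodes),
       n_contacts = as.integer(n_contacts),
       resection_corner = as.integer(resection_corner),
       resection_size = as.integer(resection_size),
       n_patients = as.integer(n_patients), outlier_rate = outlier_rate,
       jitter_sd_mm = jitter_sd_mm, outlier_shift_mm = outlier_shift_mm)
}

# centered RAS affine: world origin at the grid center
fixture_affine <- function(shape, voxel) {
  aff <- diag(c(voxel, 1))
  aff[1:3, 4] <- -voxel * (shape - 1) / 2
  aff
}

# normalized ellipsoidal radius of every voxel (1 on the brain surface)
fixture_rho <- function(shape, voxel) {
  aff <- fixture_affine(shape, voxel)
  radii <- 0.45 * shape * voxel
  ax <- lapply(1:3, function(i) ((0:(shape[i] - 1)) * voxel[i] +
                                   aff[i, 4]) / radii[i])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  sqrt(r2)
}

#' Generate a synthetic head: tissue classes and brain mask
#'
#' Nested ellipsoidal regions: a WM core (normalized radius <= 0.45), a GM
#' shell (0.45-0.85), an outer CSF shell (0.85-1), all inside an ellipsoidal
#' brain mask with semi-axes at 45% of the field of view. The affine centers
#' the world origin on the brain, RAS-oriented, so x < 0 is the left
#' hemisphere.
#'
#' @param spec A [fixture_spec()].
#' @return List with `tissue` and `mask` (`volume3d`).
#' @export
make_head <- function(spec = fixture_spec()) {
  if (any(spec$grid_shape < 16L))
    stop("make_head: grid too small to fit tissue shells (< 16 voxels/axis)",
         call. = FALSE)
  rho <- fixture_rho(spec$grid_shape, spec$voxel_size_mm)
  aff <- fixture_affine(spec$grid_shape, spec$voxel_size_mm)
  mask <- (rho <= 1) * 1
  tissue <- array(0, dim = spec$grid_shape)
  tissue[rho <= 1] <- TISSUE_CSF
  tissue[rho <= 0.85] <- TISSUE_GM
  tissue[rho <= 0.45] <- TISSUE_WM
  list(tissue = volume3d(tissue, aff, "tissue"),
       mask = volume3d(mask, aff, "mask"))
}

#' Generate a synthetic atlas over the gray-matter shell
#'
#' GM voxels are partitioned into `n_parcels` contiguous angular wedges:
#' `n_parcels / 2` sectors of the angle around the x axis, split left/right
#' by the sign of world x. Labels are 1..n with names `P01_L`, `P01_R`,
#' `P02_L`, ... and the lookup is flagged cortical, so contact labeling
#' applies the gray-matter restriction.
#'
#' @param tissue Tissue `volume3d` from [make_head()].
#' @param n_parcels Even parcel count.
#' @param atlas_name Atlas identifier in the lookup.
#' @return List with `atlas` (`volume3d`) and `lookup` (`label_lookup`).
#' @export
make_atlas <- function(tissue, n_parcels = 16L, atlas_name = "synthatlas") {
  stopifnot(inherits(tissue, "volume3d"), n_parcels %% 2L == 0L)
  d <- dim(tissue$data)
  gm <- which(tissue$data == TISSUE_GM)
  if (n_parcels > length(gm))
    stop("make_atlas: more parcels than gray-matter voxels", call. = FALSE)
  idx0 <- cbind((gm - 1) %% d[1],
                ((gm - 1) %/% d[1]) %% d[2],
                (gm - 1) %/% (d[1] * d[2]))
  w <- voxel_to_world(idx0, tissue)
  npair <- n_parcels %/% 2L
  # each hemisphere is cut into angular sectors around the x axis and, when
  # enough parcels are requested, into a medial and a lateral depth band;
  # this keeps parcel extent comparable to real cortical parcels (~10-20 mm)
  n_band <- if (npair %% 2L == 0L && npair >= 6L) 2L else 1L
  n_theta <- npair %/% n_band
  theta <- atan2(w[, 3], w[, 2])              # angle around the x axis
  sector <- pmin(floor((theta + pi) / (2 * pi) * n_theta), n_theta - 1)
  xmax <- 0.85 * 0.45 * d[1] * sqrt(sum(tissue$affine[1:3, 1]^2))
  band <- if (n_band == 2L) as.integer(abs(w[, 1]) >= xmax / 2) else 0L
  pair <- band * n_theta + sector             # 0-based pair index
  right <- w[, 1] >= 0
  lab <- 2L * pair + ifelse(right, 2L, 1L)    # pair p: 2p-1 = L, 2p = R
  atlas <- array(0, dim = d)
  atlas[gm] <- lab
  entries <- data.frame(
    label = 1:n_parcels,
    name = sprintf("P%02d_%s", rep(seq_len(npair), each = 2L), c("L", "R")),
    hemisphere = rep(c("L", "R"), npair),
    atlas = atlas_name, stringsAsFactors = FALSE)
  list(atlas = volume3d(atlas, tissue$affine, "atlas"),
       lookup = label_lookup(entries, atlas_name = atlas_name,
                             cortical = TRUE))
}

#' Generate a synthetic implantation with ground truth
#'
#' Straight electrodes radiate from near the brain center outward through
#' the mask surface along directions drawn uniformly on the sphere, with a
#' minimum angular separation so electrodes do not overlap. For every
#' contact whose 3 mm sphere lies entirely inside a single nonzero parcel
#' the ground-truth table records that parcel; contacts touching several
#' parcels or background are recorded as `"mixed"`.
#'
#' @param atlas Atlas `volume3d` from [make_atlas()].
#' @param lookup The matching `label_lookup`.
#' @param model An `electrode_model` (default: a 15-contact, 2 mm / 1.5 mm
#'   layout).
#' @param n_electrodes Number of electrodes.
#' @param seed RNG seed.
#' @param min_angle_deg Minimum angular separation between trajectories.
#' @return List with `electrodes` (list of `placed_electrode`) and `truth`
#'   (data.frame electrode, contact, parcel).
#' @export
make_implantation <- function(atlas, lookup, model = NULL, n_electrodes = 12L,
                              seed = 1L, min_angle_deg = 18) {
  stopifnot(inherits(atlas, "volume3d"))
  if (is.null(model))
    model <- electrode_model(
      "D15-synth", data.frame(n_contacts = 15L, contact_length_mm = 2,
                              gap_after_mm = 1.5))
  set.seed(seed)
  # brain semi-axes: 45% of the field of view (see make_head)
  shape <- dim(atlas$data)
  voxel <- sqrt(colSums(atlas$affine[1:3, 1:3]^2))
  rmin <- 0.45 * min(shape * voxel)
  L <- electrode_length(model)
  dirs <- matrix(numeric(0), ncol = 3L)
  offs <- matrix(numeric(0), ncol = 3L)
  attempts <- 0L
  cosmin <- cos(min_angle_deg * pi / 180)
  while (nrow(dirs) < n_electrodes) {
    attempts <- attempts + 1L
    if (attempts > 1000L)
      stop(sprintf(
        "make_implantation: could not place %d electrodes with %g deg separation after 1000 attempts",
        n_electrodes, min_angle_deg), call. = FALSE)
    v <- stats::rnorm(3L)
    v <- v / sqrt(sum(v^2))
    if (nrow(dirs) && any(abs(dirs %*% v) > cosmin)) next
    # random offset perpendicular to the trajectory keeps chords distinct
    w <- stats::rnorm(3L)
    w <- w - sum(w * v) * v
    w <- w / sqrt(sum(w^2)) * stats::runif(1L, 0, 0.2 * rmin)
    dirs <- rbind(dirs, v)
    offs <- rbind(offs, w)
  }
  names_el <- sprintf("E%02d", seq_len(n_electrodes))
  electrodes <- lapply(seq_len(n_electrodes), function(i) {
    # chord through the brain: contacts centered on the offset midpoint
    tip <- offs[i, ] - (L / 2) * dirs[i, ]
    shaft <- tip + (L + 30) * dirs[i, ]    # shaft marker outside the head
    place_electrode(model, tip, shaft, names_el[i])
  })
  truth <- do.call(rbind, lapply(electrodes, function(el) {
    parc <- vapply(seq_len(nrow(el$contact_centers)), function(ci) {
      idx <- sphere_voxels(el$contact_centers[ci, ], atlas, 3)
      if (!nrow(idx)) return("mixed")
      labs <- unique(voxel_values(atlas, idx))
      if (length(labs) == 1L && labs != 0) lookup_name(lookup, labs) else "mixed"
    }, "")
    data.frame(electrode = el$electrode_name,
               contact = seq_len(nrow(el$contact_centers)),
               parcel = parc, stringsAsFactors = FALSE)
  }))
  list(electrodes = electrodes, truth = truth)
}

#' Generate a post-operative brain mask with a carved resection block
#'
#' The post-op mask equals the pre-op mask minus an axis-aligned voxel
#' block; the ground-truth resection is the block intersected with the
#' pre-op mask.
#'
#' @param mask Pre-implantation brain mask (`volume3d`).
#' @param corner 0-based voxel corner of the block.
#' @param size Length-3 block size in voxels (all >= 1).
#' @return List with `post` and `truth` (`volume3d` masks).
#' @export
make_postop <- function(mask, corner, size) {
  stopifnot(inherits(mask, "volume3d"))
  if (length(size) != 3L || any(size < 1L))
    stop("make_postop: block size must be three positive integers",
         call. = FALSE)
  d <- dim(mask$data)
  if (any(corner < 0L) || any(corner + size > d))
    stop("make_postop: block extends outside the volume", call. = FALSE)
  block <- array(0, dim = d)
  block[(corner[1] + 1):(corner[1] + size[1]),
        (corner[2] + 1):(corner[2] + size[2]),
        (corner[3] + 1):(corner[3] + size[3])] <- 1
  truth <- block * mask$data
  if (!any(truth == 1))
    stop("make_postop: block lies entirely outside the brain mask",
         call. = FALSE)
  post <- mask$data * (1 - block)
  list(post = volume3d(post, mask$affine, "mask"),
       truth = volume3d(truth, mask$affine, "mask"))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Builds one synthetic head and atlas, then implants each of the
#' `n_patients` patients with its own randomized electrode set (the brain is
#' sampled differently between patients, as in real explorations), labels
#' every contact, and attaches randomized metadata (center, year, Engel
#' class) and stimulation events drawn from the closed vocabularies. MNI
#' positions are the contact positions in the shared fixture frame (which
#' plays the role of standard space) plus a per-patient Gaussian
#' normalization offset of sd `jitter_sd_mm`; `ceiling(outlier_rate *
#' n_patients)` patients are planted as parcellation outliers by shifting
#' all their MNI coordinates by `outlier_shift_mm` on every axis. One
#' designated patient (and only that one) has its most-implanted parcel at
#' least partially resected in its overlap report, giving a known unique
#' answer to the combined contact-in-parcel AND parcel-resected query.
#'
#' @param spec A [fixture_spec()].
#' @return List: `store` (`cohort_store`), `truth` (list with
#'   `outlier_patients`, `target_parcel`, `target_patient`, `implant_truth`,
#'   `atlas_name`, `labels`), and the template objects (`head`, `atlas`,
#'   `lookup`, `electrodes`).
#' @export
make_cohort <- function(spec = fixture_spec()) {
  head <- make_head(spec)
  atl <- make_atlas(head$tissue, spec$n_parcels)
  model <- electrode_model(
    "D-synth", data.frame(n_contacts = spec$n_contacts,
                          contact_length_mm = 2, gap_after_mm = 1.5))
  atlas_name <- attr(atl$lookup, "atlas_name")
  lab_col <- paste0(atlas_name, "_name")
  atlases <- list()
  atlases[[atlas_name]] <- list(volume = atl$atlas, lookup = atl$lookup)

  # one implantation per patient: the brain is sampled differently between
  # patients, which also makes per-parcel clouds fill the parcel volume
  implants <- vector("list", spec$n_patients)
  all_labels <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    imp_i <- make_implantation(atl$atlas, atl$lookup, model = model,
                               n_electrodes = spec$n_electrodes,
                               seed = spec$seed + 7919L * i)
    implants[[i]] <- imp_i
    all_labels[[i]] <- label_all(imp_i$electrodes, atlases = atlases,
                                 tissue = head$tissue)
  }

  labels1 <- all_labels[[1L]]
  labeled1 <- labels1[[lab_col]][labels1[[lab_col]] != "unlabeled"]
  if (!length(labeled1))
    stop("make_cohort: no contact received a parcel label", call. = FALSE)
  target_parcel <- names(sort(table(labeled1), decreasing = TRUE))[1L]
  other_parcels <- setdiff(atl$lookup$name, target_parcel)

  set.seed(spec$seed + 1L)
  n <- spec$n_patients
  n_out <- ceiling(spec$outlier_rate * n)
  ids <- sprintf("P%03d", seq_len(n))
  outlier_patients <- sort(sample(ids, n_out))
  target_patient <- ids[1L]

  store <- cohort_store()
  for (i in seq_len(n)) {
    id <- ids[i]
    imp <- implants[[i]]
    labels <- all_labels[[i]]
    mni <- labels[, c("electrode", "contact", "x", "y", "z")]
    # normalization error is a per-patient offset: every contact of a
    # patient shares the same Gaussian jitter
    jit <- stats::rnorm(3L, sd = spec$jitter_sd_mm)
    mni[, c("x", "y", "z")] <- sweep(as.matrix(mni[, c("x", "y", "z")]),
                                     2L, jit, `+`)
    if (id %in% outlier_patients)
      mni[, c("x", "y", "z")] <- mni[, c("x", "y", "z")] + spec$outlier_shift_mm
    events <- list()
    for (el in imp$electrodes) {
      ca <- sample(nrow(el$contact_centers) - 1L, 1L)
      events[[length(events) + 1L]] <- stimulation_event(
        el$electrode_name, ca, ca + 1L,
        frequency_hz = sample(STIM_FREQUENCIES, 1L),
        response_category = sample(RESPONSE_CATEGORIES, 1L, prob = c(.2, .4, .3, .1)),
        classifications = character(0), intensity_ma = sample(c(1, 2, 3), 1L))
    }
    events <- lapply(events, function(ev) {
      if (ev$response_category %in% c("response_non_epileptic", "seizure_like") &&
          stats::runif(1) < 0.7)
        ev$classifications <- sort(sample(STIM_CLASSIFICATIONS,
                                          sample(1:2, 1L)))
      ev
    })
    resected <- (id == target_patient) || stats::runif(1) < 0.5
    overlap <- NULL
    if (resected) {
      pars <- sample(other_parcels, sample(1:2, 1L))
      if (id == target_patient) pars <- c(target_parcel, pars[1L])
      pct <- round(stats::runif(length(pars), 5, 80), 1)
      pp <- data.frame(atlas = atlas_name,
                       label = atl$lookup$label[match(pars, atl$lookup$name)],
                       name = pars,
                       parcel_voxels = 1000L,
                       resected_voxels = as.integer(round(10 * pct)),
                       percent = pct, stringsAsFactors = FALSE)
      pp <- pp[order(pp$label), , drop = FALSE]
      rownames(pp) <- NULL
      overlap <- structure(list(total_volume_mm3 = sum(pp$resected_voxels),
                                per_parcel = pp,
                                brain_shift_unreliable = TRUE),
                           class = "overlap_report")
    }
    rec <- patient_record(
      id, center = sample(c("CenterA", "CenterB", "CenterC"), 1L),
      year = sample(2008:2020, 1L),
      engel_class = sample(ENGEL_CLASSES, 1L, prob = c(.35, .25, .15, .1, .15)),
      electrodes = imp$electrodes, contact_labels = labels,
      overlap_report = overlap, stimulation_events = events,
      mni_coords = mni)
    store <- add_patient(store, rec)
  }
  list(store = store,
       truth = list(outlier_patients = outlier_patients,
                    target_parcel = target_parcel,
                    target_patient = target_patient,
                    implant_truth = implants[[1L]]$truth,
                    atlas_name = atlas_name, labels = labels1),
       head = head, atlas = atl$atlas, lookup = atl$lookup,
       electrodes = implants[[1L]]$electrodes)
}
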