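# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately use plain loops / direct formulas so they share
# no code path with the implementation they check.

# a volume on a given grid with random content
rand_volume <- function(dim3, kind = "atlas", affine = NULL, nlab = 5L) {
  if (is.null(affine)) affine <- diag(4)
  data <- switch(kind,
    atlas = array(sample(0:nlab, prod(dim3), replace = TRUE), dim = dim3),
    tissue = array(sample(0:3, prod(dim3), replace = TRUE), dim = dim3),
    mask = array(sample(0:1, prod(dim3), replace = TRUE), dim = dim3),
    statmap = array(stats::rnorm(prod(dim3)), dim = dim3))
  volume3d(data, affine, kind)
}

# random rigid transform: rotation from QR decomposition + translation
rand_rigid <- function(max_shift = 5) {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- stats::runif(3, -max_shift, max_shift)
  rigid_transform(m)
}

# random affine with anisotropic spacing, optional rotation, random origin
rand_affine <- function(rotate = TRUE) {
  sp <- stats::runif(3, 0.5, 3)
  aff <- diag(c(sp, 1))
  if (rotate) {
    qr_ <- qr(matrix(stats::rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    aff[1:3, 1:3] <- R %*% diag(sp)
  }
  aff[1:3, 4] <- stats::runif(3, -10, 10)
  aff
}

# oracle: all in-bounds voxels whose centers are within radius of center,
# by exhaustive loop over every voxel
oracle_sphere <- function(center, vol, radius) {
  d <- dim(vol$data)
  hits <- NULL
  for (i in 0:(d[1] - 1)) for (j in 0:(d[2] - 1)) for (k in 0:(d[3] - 1)) {
    w <- vol$affine %*% c(i, j, k, 1)
    if (sum((w[1:3] - center)^2) <= radius^2 + 1e-12)
      hits <- rbind(hits, c(i, j, k))
  }
  if (is.null(hits)) matrix(integer(0), ncol = 3) else
    hits[order(hits[, 1], hits[, 2], hits[, 3]), , drop = FALSE]
}

# oracle: modal atlas label via explicit counting (same tie-break contract:
# smallest label on ties)
oracle_label_atlas <- function(center, atlas, tissue, radius, cortical) {
  idx <- oracle_sphere(center, atlas, radius)
  if (!nrow(idx)) return(0L)
  labs <- apply(idx, 1, function(v) atlas$data[v[1] + 1, v[2] + 1, v[3] + 1])
  keep <- labs != 0
  if (!is.null(tissue) && cortical) {
    tis <- apply(idx, 1, function(v) tissue$data[v[1] + 1, v[2] + 1, v[3] + 1])
    keep <- keep & tis == 2
  }
  labs <- labs[keep]
  if (!length(labs)) return(0L)
  counts <- table(labs)
  as.integer(min(as.integer(names(counts)[counts == max(counts)])))
}

oracle_label_tissue <- function(center, tissue, radius) {
  idx <- oracle_sphere(center, tissue, radius)
  if (!nrow(idx)) return("unlabeled")
  v <- apply(idx, 1, function(x) tissue$data[x[1] + 1, x[2] + 1, x[3] + 1])
  v <- v[v != 0]
  if (!length(v)) return("unlabeled")
  counts <- c(GM = sum(v == 2), WM = sum(v == 3), CSF = sum(v == 1))
  names(counts)[which.max(counts)]
}

# oracle: per-voxel nearest-neighbour resampling by explicit loop
oracle_resample <- function(src, target, t) {
  d <- dim(target$data)
  out <- array(0, dim = d)
  M <- solve(src$affine) %*% unclass(t) %*% target$affine
  ds <- dim(src$data)
  for (i in 0:(d[1] - 1)) for (j in 0:(d[2] - 1)) for (k in 0:(d[3] - 1)) {
    sv <- round(M %*% c(i, j, k, 1))[1:3]
    if (all(sv >= 0) && all(sv < ds))
      out[i + 1, j + 1, k + 1] <- src$data[sv[1] + 1, sv[2] + 1, sv[3] + 1]
  }
  out
}

# oracle: binary erosion / dilation / opening with the 6-connected cross,
# explicit neighbour checks
oracle_opening <- function(a) {
  d <- dim(a)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  er <- array(0, dim = d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (a[i, j, k] != 1) next
    ok <- TRUE
    for (r in 1:6) {
      p <- c(i, j, k) + nb[r, ]
      if (any(p < 1) || any(p > d) || a[p[1], p[2], p[3]] != 1) { ok <- FALSE; break }
    }
    er[i, j, k] <- as.numeric(ok)
  }
  di <- array(0, dim = d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (er[i, j, k] == 1) { di[i, j, k] <- 1; next }
    for (r in 1:6) {
      p <- c(i, j, k) + nb[r, ]
      if (!any(p < 1) && !any(p > d) && er[p[1], p[2], p[3]] == 1) {
        di[i, j, k] <- 1; break
      }
    }
  }
  di
}

# oracle: MAD flags by direct formula evaluation
oracle_mad <- function(pts, k = 4) {
  if (nrow(pts) < 3) return(rep(FALSE, nrow(pts)))
  ctr <- apply(pts, 2, median)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  d > k * median(d)
}

# oracle: Chauvenet flags by direct per-axis formula (erfc via pracma)
oracle_chauvenet <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(rep(FALSE, n))
  flags <- rep(FALSE, n)
  for (ax in 1:3) {
    x <- pts[, ax]
    s <- sqrt(mean((x - mean(x))^2))
    if (s <= 0) next
    flags <- flags | (n * pracma::erfc(abs(x - mean(x)) / s) < 0.5)
  }
  flags
}

# oracle: brute-force conjunctive filter over all patient records
oracle_query <- function(store, center = NULL, year_range = NULL,
                         engel_class = NULL, contact_in_parcel = NULL,
                         resected_parcel = NULL) {
  hits <- character(0)
  for (id in names(store$patients)) {
    rec <- store$patients[[id]]
    pass <- TRUE
    if (!is.null(center)) pass <- pass && rec$center == center
    if (!is.null(year_range))
      pass <- pass && rec$year >= year_range[1] && rec$year <= year_range[2]
    if (!is.null(engel_class)) pass <- pass && rec$engel_class %in% engel_class
    if (!is.null(contact_in_parcel)) {
      col <- paste0(contact_in_parcel$atlas, "_name")
      pass <- pass && !is.null(rec$contact_labels) &&
        col %in% names(rec$contact_labels) &&
        contact_in_parcel$name %in% rec$contact_labels[[col]]
    }
    if (!is.null(resected_parcel)) {
      minp <- if (is.null(resected_parcel$min_percent)) 0 else
        resected_parcel$min_percent
      ok <- FALSE
      if (!is.null(rec$overlap_report)) {
        pp <- rec$overlap_report$per_parcel
        ok <- any(pp$atlas == resected_parcel$atlas &
                    pp$name == resected_parcel$name & pp$percent > minp)
      }
      pass <- pass && ok
    }
    if (pass) hits <- c(hits, id)
  }
  sort(hits)
}

# a compact cohort spec used by unit tests (full defaults are exercised in
# the acceptance suite)
small_cohort_spec <- function(seed = 7L, n_patients = 6L) {
  fixture_spec(grid_shape = c(32L, 32L, 32L), seed = seed,
               n_parcels = 8L, n_electrodes = 3L, n_contacts = 5L,
               resection_corner = c(18L, 18L, 18L),
               resection_size = c(4L, 4L, 4L),
               n_patients = n_patients)
}

simple_lookup <- function(n = 5L, atlas = "toy", cortical = FALSE) {
  label_lookup(data.frame(label = seq_len(n),
                          name = sprintf("p%02d", seq_len(n)),
                          hemisphere = "none", atlas = atlas,
                          stringsAsFactors = FALSE),
               atlas_name = atlas, cortical = cortical)
}
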