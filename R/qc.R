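# Group-level parcellation quality control: for each parcel, the cloud of
# contact MNI positions pooled over patients is screened for outliers with
# the 4xMAD rule (on distances to the component-wise median) and the
# Chauvenet criterion (per axis, n * erfc(|x - mean| / std) < 0.5).

# complementary error function via the normal tail
erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' MAD-rule outlier flags for a parcel's contact cloud
#'
#' With `X` the dataset of contact positions, the median absolute deviation
#' is `MAD = median(|X_i - median(X)|)` — here the median Euclidean distance
#' `d_i` of the points to the component-wise median position — and point i
#' is flagged when it lies further than `k` times the MAD from the median:
#' `d_i > k * MAD` (default k = 4). Clouds with fewer than 3 points are
#' reported as insufficient and never flagged.
#'
#' Working on distances rather than per-axis coordinates makes the flags
#' invariant under rotation as well as translation; per-axis screening
#' (deviation `|x_i - median(x)|` against `k` times the per-axis MAD) is
#' available with `per_axis = TRUE`.
#'
#' @param points Numeric n x 3 matrix of MNI mm coordinates.
#' @param k Flagging multiplier (default 4).
#' @param per_axis If TRUE, apply the rule per coordinate axis instead
#'   (flag if exceeded on any axis).
#' @return List: `flags` (logical n), `stats` (list with n, mean, median,
#'   mad, threshold, distances), `insufficient_n`.
#' @export
mad_outliers <- function(points, k = 4, per_axis = FALSE) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  base_stats <- list(n = n, mean = colMeans(pts),
                     median = apply(pts, 2L, stats::median))
  if (n < 3L)
    return(list(flags = rep(FALSE, n),
                stats = c(base_stats, list(mad = NA_real_, threshold = NA_real_)),
                insufficient_n = TRUE))
  if (per_axis) {
    flags <- rep(FALSE, n)
    mads <- numeric(3L)
    for (ax in 1:3) {
      dev <- abs(pts[, ax] - stats::median(pts[, ax]))
      mads[ax] <- stats::median(dev)
      flags <- flags | (dev > k * mads[ax])
    }
    return(list(flags = flags,
                stats = c(base_stats, list(mad = mads, threshold = k * mads)),
                insufficient_n = FALSE))
  }
  ctr <- base_stats$median
  d <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
  madv <- stats::median(d)
  flags <- d > k * madv
  list(flags = flags,
       stats = c(base_stats,
                 list(mad = madv, threshold = k * madv, distances = d)),
       insufficient_n = FALSE)
}

#' Chauvenet-criterion outlier flags for a parcel's contact cloud
#'
#' Applied per coordinate axis: with the axis mean and population standard
#' deviation, point i is flagged on that axis when
#' `n * erfc(|x_i - mean| / std) < 0.5`; a point is suspicious if flagged on
#' at least one axis. The criterion is used exactly in this form by default
#' — the scaled residual is NOT divided by sqrt(2) — which is deliberately
#' more aggressive than the textbook Chauvenet test; `classic = TRUE`
#' restores the sqrt(2) factor. Zero-variance axes are skipped, and clouds
#' with fewer than 3 points are reported as insufficient.
#'
#' @param points Numeric n x 3 matrix of MNI mm coordinates.
#' @param classic If TRUE, use the textbook form
#'   `n * erfc(|x - mean| / (std * sqrt(2))) < 0.5`.
#' @return List: `flags` (logical n), `stats` (n, mean, median, sd per axis),
#'   `insufficient_n`.
#' @export
chauvenet_outliers <- function(points, classic = FALSE) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  sds <- apply(pts, 2L, function(x) sqrt(mean((x - mean(x))^2)))  # population
  base_stats <- list(n = n, mean = colMeans(pts),
                     median = apply(pts, 2L, stats::median), sd = sds)
  if (n < 3L)
    return(list(flags = rep(FALSE, n), stats = base_stats,
                insufficient_n = TRUE))
  flags <- rep(FALSE, n)
  for (ax in 1:3) {
    if (sds[ax] <= 0) next
    z <- abs(pts[, ax] - base_stats$mean[ax]) / sds[ax]
    if (classic) z <- z / sqrt(2)
    flags <- flags | (n * erfc_(z) < 0.5)
  }
  list(flags = flags, stats = base_stats, insufficient_n = FALSE)
}

#' Suspicious-parcellation report over a cohort
#'
#' For every parcel of `atlas`, the MNI positions of all contacts labeled
#' with that parcel are pooled across patients and screened with
#' [mad_outliers()] and/or [chauvenet_outliers()]. Each flagged contact
#' yields one row per flagging method; a contact far from its parcel's
#' cluster suggests a wrong parcellation (or wrong MNI normalization) for
#' that patient. Parcels with fewer than 3 contacts are skipped and listed
#' in the `skipped_parcels` attribute.
#'
#' @param store A cohort store (see [cohort_store()]).
#' @param atlas Atlas name used in the patients' contact labels.
#' @param methods Subset of `c("mad", "chauvenet")`.
#' @param mad_k MAD multiplier (default 4).
#' @param classic Use the textbook Chauvenet form (default FALSE).
#' @return data.frame (patient_id, electrode, contact, parcel, method,
#'   deviation, threshold, n_cloud) sorted deterministically; attributes
#'   `skipped_parcels` and `patients_without_mni`.
#' @export
qc_report <- function(store, atlas, methods = c("mad", "chauvenet"),
                      mad_k = 4, classic = FALSE) {
  methods <- match.arg(methods, c("mad", "chauvenet"), several.ok = TRUE)
  cloud <- export_group_cloud(store, atlas)
  if (nrow(cloud) == 0L) {
    warning("qc_report: no patient has MNI coordinates; empty report")
    out <- data.frame(patient_id = character(0), electrode = character(0),
                      contact = integer(0), parcel = character(0),
                      method = character(0), deviation = numeric(0),
                      threshold = numeric(0), n_cloud = integer(0))
    attr(out, "skipped_parcels") <- character(0)
    return(out)
  }
  cloud <- cloud[cloud$parcel != "unlabeled", , drop = FALSE]
  rows <- list()
  skipped <- character(0)
  for (p in sort(unique(cloud$parcel))) {
    sub <- cloud[cloud$parcel == p, , drop = FALSE]
    pts <- as.matrix(sub[, c("mni_x", "mni_y", "mni_z")])
    if (nrow(pts) < 3L) { skipped <- c(skipped, p); next }
    if ("mad" %in% methods) {
      r <- mad_outliers(pts, k = mad_k)
      w <- which(r$flags)
      if (length(w))
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sub$patient_id[w], electrode = sub$electrode[w],
          contact = sub$contact[w], parcel = p, method = "mad",
          deviation = r$stats$distances[w], threshold = r$stats$threshold,
          n_cloud = nrow(pts), stringsAsFactors = FALSE)
    }
    if ("chauvenet" %in% methods) {
      r <- chauvenet_outliers(pts, classic = classic)
      w <- which(r$flags)
      if (length(w)) {
        z <- apply(abs(sweep(pts[w, , drop = FALSE], 2L, r$stats$mean)) /
                     pmax(r$stats$sd, .Machine$double.eps), 1L, max)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sub$patient_id[w], electrode = sub$electrode[w],
          contact = sub$contact[w], parcel = p, method = "chauvenet",
          deviation = z, threshold = NA_real_,
          n_cloud = nrow(pts), stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), electrode = character(0),
               contact = integer(0), parcel = character(0),
               method = character(0), deviation = numeric(0),
               threshold = numeric(0), n_cloud = integer(0))
  out <- out[order(out$parcel, out$method, out$patient_id, out$electrode,
                   out$contact), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_parcels") <- skipped
  attr(out, "patients_without_mni") <- attr(cloud, "patients_without_mni")
  out
}

#' Write a QC report to CSV
#'
#' Skipped (too-small) parcels are listed in `#`-prefixed footer lines.
#' @param report data.frame from [qc_report()].
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(report, con, row.names = FALSE)
  sk <- attr(report, "skipped_parcels")
  if (length(sk))
    writeLines(paste0("# insufficient data (n < 3): ",
                      paste(sk, collapse = "; ")), con)
  invisible(path)
}
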