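# Multi-criteria patient cohort store: patient records (electrodes, contact
# labels, resection overlap, stimulation events, surgical outcome, MNI
# contact coordinates) persisted as a single deterministic JSON document
# store, with conjunctive query semantics.

ENGEL_CLASSES <- c("I", "II", "III", "IV", "unknown")
STIM_FREQUENCIES <- c(1, 50)
RESPONSE_CATEGORIES <- c("not_stimulated", "no_response",
                         "response_non_epileptic", "seizure_like")
STIM_CLASSIFICATIONS <- c("motor", "sensitive", "sensory", "vegetative",
                          "emotional", "experiential", "superior_function")

#' Construct a stimulation event
#'
#' A bipolar stimulation of two adjacent contacts of one electrode at 1 or
#' 50 Hz. The clinical response is one of a closed vocabulary
#' (`not_stimulated`, `no_response`, `response_non_epileptic`,
#' `seizure_like`) and may carry semiology classifications (`motor`,
#' `sensitive`, `sensory`, `vegetative`, `emotional`, `experiential`,
#' `superior_function`). These enumerations replace the color coding used on
#' clinical stimulation sheets (gray = not stimulated, black = no response,
#' red = motor, blue = sensitive, green = sensory, yellow = vegetative,
#' purple = emotional, pink = experiential, brown = superior function).
#'
#' @param electrode Electrode name.
#' @param contact_a,contact_b Adjacent contact indices (|a - b| = 1).
#' @param frequency_hz 1 or 50.
#' @param response_category One of the response vocabulary.
#' @param classifications Character vector, subset of the semiology
#'   vocabulary; must be empty when `response_category = "not_stimulated"`.
#' @param intensity_ma Optional stimulation intensity (mA > 0).
#' @export
stimulation_event <- function(electrode, contact_a, contact_b, frequency_hz,
                              response_category, classifications = character(0),
                              intensity_ma = NA_real_) {
  if (abs(contact_a - contact_b) != 1L)
    stop(sprintf("stimulation_event: bipole contacts must be adjacent (got %d and %d)",
                 contact_a, contact_b), call. = FALSE)
  if (!frequency_hz %in% STIM_FREQUENCIES)
    stop(sprintf("stimulation_event: frequency must be 1 or 50 Hz (got %g)",
                 frequency_hz), call. = FALSE)
  if (!response_category %in% RESPONSE_CATEGORIES)
    stop("stimulation_event: unknown response_category '", response_category,
         "'", call. = FALSE)
  bad <- setdiff(classifications, STIM_CLASSIFICATIONS)
  if (length(bad))
    stop("stimulation_event: unknown classification(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (response_category == "not_stimulated" && length(classifications))
    stop("stimulation_event: a not_stimulated bipole cannot carry classifications",
         call. = FALSE)
  if (!is.na(intensity_ma) && intensity_ma <= 0)
    stop("stimulation_event: intensity_ma must be positive", call. = FALSE)
  structure(list(electrode = as.character(electrode),
                 contact_a = as.integer(contact_a),
                 contact_b = as.integer(contact_b),
                 frequency_hz = as.numeric(frequency_hz),
                 intensity_ma = as.numeric(intensity_ma),
                 response_category = response_category,
                 classifications = sort(as.character(classifications))),
            class = "stimulation_event")
}

#' Construct a patient record
#'
#' One implanted patient: metadata (center, acquisition year, Engel surgical
#' outcome class), placed electrodes, the contact-label table, an optional
#' resection overlap report, stimulation events, and optional per-contact
#' MNI coordinates.
#'
#' @param patient_id Unique identifier.
#' @param center Acquisition center name.
#' @param year 4-digit acquisition year.
#' @param engel_class One of I, II, III, IV, unknown.
#' @param electrodes List of `placed_electrode`.
#' @param contact_labels data.frame from [label_all()] (or compatible).
#' @param overlap_report Optional `overlap_report`.
#' @param stimulation_events List of `stimulation_event`.
#' @param mni_coords Optional data.frame (electrode, contact, x, y, z) of
#'   contact positions in MNI mm.
#' @export
patient_record <- function(patient_id, center, year,
                           engel_class = "unknown", electrodes = list(),
                           contact_labels = NULL, overlap_report = NULL,
                           stimulation_events = list(), mni_coords = NULL) {
  if (!is.character(patient_id) || length(patient_id) != 1L || !nzchar(patient_id))
    stop("patient_record: patient_id must be a non-empty string", call. = FALSE)
  year <- as.integer(year)
  if (is.na(year) || year < 1000L || year > 9999L)
    stop("patient_record: year must be a plausible 4-digit integer", call. = FALSE)
  if (!engel_class %in% ENGEL_CLASSES)
    stop("patient_record: engel_class must be one of ",
         paste(ENGEL_CLASSES, collapse = ", "), call. = FALSE)
  ncont <- stats::setNames(
    vapply(electrodes, function(e) nrow(e$contact_centers), 0L),
    vapply(electrodes, `[[`, "", "electrode_name"))
  if (anyDuplicated(names(ncont)))
    stop("patient_record: duplicate electrode names", call. = FALSE)
  for (ev in stimulation_events) {
    if (!ev$electrode %in% names(ncont))
      stop(sprintf("patient_record '%s': stimulation references unknown electrode '%s'",
                   patient_id, ev$electrode), call. = FALSE)
    if (max(ev$contact_a, ev$contact_b) > ncont[[ev$electrode]])
      stop(sprintf("patient_record '%s': stimulation references contact %s%d but the electrode has %d contacts",
                   patient_id, ev$electrode, max(ev$contact_a, ev$contact_b),
                   ncont[[ev$electrode]]), call. = FALSE)
  }
  if (!is.null(mni_coords)) {
    need <- c("electrode", "contact", "x", "y", "z")
    if (!all(need %in% names(mni_coords)))
      stop("patient_record: mni_coords needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    mni_coords <- as.data.frame(mni_coords)[need]
  }
  structure(list(patient_id = patient_id, center = as.character(center),
                 year = year, engel_class = engel_class,
                 electrodes = electrodes, contact_labels = contact_labels,
                 overlap_report = overlap_report,
                 stimulation_events = stimulation_events,
                 mni_coords = mni_coords),
            class = "patient_record")
}

#' Create an empty cohort store
#'
#' The store is an in-memory collection of patient records persisted as a
#' single JSON document file ([save_store()] / [load_store()]) whose
#' serialization is deterministic: saving the same store twice is
#' byte-identical.
#' @export
cohort_store <- function() {
  structure(list(patients = list()), class = "cohort_store")
}

#' Add a patient record to a store
#'
#' @param store A `cohort_store`.
#' @param rec A `patient_record`.
#' @param overwrite Replace an existing record with the same id.
#' @return The updated store.
#' @export
add_patient <- function(store, rec, overwrite = FALSE) {
  stopifnot(inherits(store, "cohort_store"), inherits(rec, "patient_record"))
  if (!overwrite && rec$patient_id %in% names(store$patients))
    stop("add_patient: duplicate patient_id '", rec$patient_id,
         "' (use overwrite = TRUE to replace)", call. = FALSE)
  store$patients[[rec$patient_id]] <- rec
  store
}

#' Number of patients in a store
#' @param store A `cohort_store`.
#' @export
n_patients <- function(store) length(store$patients)

#' @export
print.cohort_store <- function(x, ...) {
  cat(sprintf("<cohort_store: %d patient(s)>\n", n_patients(x)))
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

record_to_list <- function(rec) {
  out <- list(
    patient_id = rec$patient_id, center = rec$center, year = rec$year,
    engel_class = rec$engel_class,
    electrodes = lapply(rec$electrodes, function(e) list(
      electrode_name = e$electrode_name,
      model = list(model_name = e$model$model_name,
                   diameter_mm = e$model$diameter_mm,
                   tip_offset_mm = e$model$tip_offset_mm,
                   segments = e$model$segments),
      tip_point = e$tip_point, shaft_point = e$shaft_point)),
    contact_labels = rec$contact_labels,
    overlap_report = if (!is.null(rec$overlap_report)) list(
      total_volume_mm3 = rec$overlap_report$total_volume_mm3,
      brain_shift_unreliable = rec$overlap_report$brain_shift_unreliable,
      per_parcel = rec$overlap_report$per_parcel),
    stimulation_events = lapply(rec$stimulation_events, unclass),
    mni_coords = rec$mni_coords)
  out[!vapply(out, is.null, logical(1L))]
}

record_from_list <- function(x) {
  electrodes <- lapply(x$electrodes, function(e) {
    segs <- as.data.frame(do.call(rbind, lapply(e$model$segments, as.data.frame)))
    mdl <- electrode_model(e$model$model_name, segs,
                           diameter_mm = e$model$diameter_mm,
                           tip_offset_mm = e$model$tip_offset_mm)
    place_electrode(mdl, unlist(e$tip_point), unlist(e$shaft_point),
                    e$electrode_name)
  })
  labels <- if (length(x$contact_labels))
    df_from_json(x$contact_labels)
  overlap <- if (length(x$overlap_report))
    structure(list(total_volume_mm3 = x$overlap_report$total_volume_mm3,
                   per_parcel = df_from_json(x$overlap_report$per_parcel),
                   brain_shift_unreliable = isTRUE(x$overlap_report$brain_shift_unreliable)),
              class = "overlap_report")
  events <- lapply(x$stimulation_events, function(ev)
    stimulation_event(ev$electrode, ev$contact_a, ev$contact_b,
                      ev$frequency_hz, ev$response_category,
                      classifications = unlist(ev$classifications) %||% character(0),
                      intensity_ma = ev$intensity_ma %||% NA_real_))
  mni <- if (length(x$mni_coords)) df_from_json(x$mni_coords)
  patient_record(x$patient_id, x$center, x$year, x$engel_class,
                 electrodes = electrodes, contact_labels = labels,
                 overlap_report = overlap, stimulation_events = events,
                 mni_coords = mni)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rows-of-objects JSON back to data.frame
df_from_json <- function(x) {
  if (is.data.frame(x)) return(x)
  rows <- lapply(x, function(r)
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Save a cohort store to a JSON file
#'
#' Patients are written sorted by id with full numeric precision, so
#' saving the same cohort always produces byte-identical output.
#' @param store A `cohort_store`.
#' @param path Output path.
#' @export
save_store <- function(store, path) {
  ids <- sort(names(store$patients))
  obj <- list(format = "seegloc-cohort", version = 1L,
              patients = lapply(store$patients[ids], record_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a cohort store from a JSON file
#' @param path File written by [save_store()].
#' @export
load_store <- function(path) {
  if (!file.exists(path))
    stop("load_store: file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "seegloc-cohort"))
    stop("load_store: not a cohort store file", call. = FALSE)
  store <- cohort_store()
  for (p in obj$patients) store <- add_patient(store, record_from_list(p))
  store
}

# ---- stimulation table import ----------------------------------------------

parse_bipole <- function(s) {
  m <- regmatches(s, regexec("^(.*?)([0-9]+)-(?:.*?)([0-9]+)$", s))[[1L]]
  if (length(m) != 4L)
    stop("cannot parse bipole '", s, "' (expected e.g. \"Q'1-Q'2\" or \"Q'1-2\")",
         call. = FALSE)
  list(electrode = m[2L], a = as.integer(m[3L]), b = as.integer(m[4L]))
}

#' Import a stimulation-session table
#'
#' Reads a CSV with explicit columns `bipole` (e.g. `"Q'1-Q'2"`),
#' `frequency_hz`, `intensity_ma` (optional values), `response_category` and
#' `classifications` (semicolon-separated), validates every row against the
#' closed vocabularies and the patient's electrodes, and returns the events.
#' Invalid rows raise an error naming the row number.
#'
#' @param path CSV file path.
#' @param patient `patient_record` the events belong to.
#' @return List of `stimulation_event`.
#' @export
import_stim_table <- function(path, patient) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bipole", "frequency_hz", "response_category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("import_stim_table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ncont <- stats::setNames(
    vapply(patient$electrodes, function(e) nrow(e$contact_centers), 0L),
    vapply(patient$electrodes, `[[`, "", "electrode_name"))
  events <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ev <- tryCatch({
      bp <- parse_bipole(df$bipole[i])
      if (!bp$electrode %in% names(ncont))
        stop("unknown electrode '", bp$electrode, "'", call. = FALSE)
      if (max(bp$a, bp$b) > ncont[[bp$electrode]])
        stop(sprintf("contact %s%d does not exist (electrode has %d contacts)",
                     bp$electrode, max(bp$a, bp$b), ncont[[bp$electrode]]),
             call. = FALSE)
      cls <- df$classifications[i] %||% ""
      cls <- if (is.na(cls) || !nzchar(cls)) character(0) else
        strsplit(cls, ";", fixed = TRUE)[[1L]]
      inten <- if ("intensity_ma" %in% names(df)) df$intensity_ma[i] else NA_real_
      stimulation_event(bp$electrode, bp$a, bp$b, df$frequency_hz[i],
                        df$response_category[i], classifications = trimws(cls),
                        intensity_ma = inten)
    }, error = function(e)
      stop(sprintf("import_stim_table: row %d: %s", i, conditionMessage(e)),
           call. = FALSE))
    events[[i]] <- ev
  }
  events
}

# ---- queries ----------------------------------------------------------------

# parcel names a contact-label table assigns for an atlas
labels_for_atlas <- function(rec, atlas) {
  col <- paste0(atlas, "_name")
  if (is.null(rec$contact_labels) || !col %in% names(rec$contact_labels))
    return(character(0))
  rec$contact_labels[[col]]
}

known_atlases <- function(store) {
  unique(unlist(lapply(store$patients, function(r) {
    cols <- grep("_name$", names(r$contact_labels), value = TRUE)
    c(sub("_name$", "", cols),
      if (!is.null(r$overlap_report)) r$overlap_report$per_parcel$atlas)
  })))
}

known_parcels <- function(store, atlas) {
  unique(unlist(lapply(store$patients, function(r) {
    c(labels_for_atlas(r, atlas),
      if (!is.null(r$overlap_report)) {
        pp <- r$overlap_report$per_parcel
        pp$name[pp$atlas == atlas]
      })
  })))
}

check_parcel_criterion <- function(store, crit, what) {
  if (is.null(crit$atlas) || is.null(crit$name))
    stop("query: ", what, " needs fields `atlas` and `name`", call. = FALSE)
  if (!crit$atlas %in% known_atlases(store))
    stop("query: unknown atlas '", crit$atlas, "'", call. = FALSE)
  if (!crit$name %in% known_parcels(store, crit$atlas))
    stop("query: unknown parcel '", crit$name, "' in atlas '", crit$atlas,
         "'", call. = FALSE)
}

#' Query a cohort with conjunctive criteria
#'
#' All provided criteria must hold simultaneously (logical AND); omitted
#' criteria do not constrain. With no criteria, every patient matches. The
#' semantics are those of a brute-force filter over all records; results are
#' sorted by patient id.
#'
#' @param store A `cohort_store`.
#' @param center Acquisition center (exact match).
#' @param year_range Length-2 inclusive year interval.
#' @param engel_class Character vector of acceptable Engel classes.
#' @param contact_in_parcel `list(atlas=, name=)`: at least one contact
#'   labeled with the parcel.
#' @param resected_parcel `list(atlas=, name=, min_percent=)`: the parcel
#'   appears in the overlap report above `min_percent` (default 0,
#'   strict — "at least partially resected").
#' @param stimulated_parcel `list(atlas=, name=, frequency=, response_category=,
#'   classification=, both_contacts=)`: some stimulation event matching the
#'   optional frequency/response/classification filters has a bipole located
#'   in the parcel — by default through either of its two contact labels,
#'   or both when `both_contacts = TRUE`.
#' @return Sorted character vector of matching patient ids.
#' @export
query <- function(store, center = NULL, year_range = NULL, engel_class = NULL,
                  contact_in_parcel = NULL, resected_parcel = NULL,
                  stimulated_parcel = NULL) {
  stopifnot(inherits(store, "cohort_store"))
  if (!is.null(engel_class)) {
    bad <- setdiff(engel_class, ENGEL_CLASSES)
    if (length(bad))
      stop("query: unknown Engel class: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(contact_in_parcel))
    check_parcel_criterion(store, contact_in_parcel, "contact_in_parcel")
  if (!is.null(resected_parcel))
    check_parcel_criterion(store, resected_parcel, "resected_parcel")
  if (!is.null(stimulated_parcel))
    check_parcel_criterion(store, stimulated_parcel, "stimulated_parcel")

  ok <- vapply(store$patients, function(rec) {
    if (!is.null(center) && rec$center != center) return(FALSE)
    if (!is.null(year_range) &&
        (rec$year < year_range[1L] || rec$year > year_range[2L])) return(FALSE)
    if (!is.null(engel_class) && !rec$engel_class %in% engel_class) return(FALSE)
    if (!is.null(contact_in_parcel) &&
        !contact_in_parcel$name %in%
          labels_for_atlas(rec, contact_in_parcel$atlas)) return(FALSE)
    if (!is.null(resected_parcel)) {
      minp <- resected_parcel$min_percent %||% 0
      if (is.null(rec$overlap_report)) return(FALSE)
      pp <- rec$overlap_report$per_parcel
      hit <- pp$atlas == resected_parcel$atlas &
        pp$name == resected_parcel$name & pp$percent > minp
      if (!any(hit)) return(FALSE)
    }
    if (!is.null(stimulated_parcel) &&
        !patient_has_stim_in_parcel(rec, stimulated_parcel)) return(FALSE)
    TRUE
  }, logical(1L))
  sort(names(store$patients)[ok])
}

patient_has_stim_in_parcel <- function(rec, crit) {
  col <- paste0(crit$atlas, "_name")
  labs <- rec$contact_labels
  if (is.null(labs) || !col %in% names(labs)) return(FALSE)
  both <- isTRUE(crit$both_contacts)
  for (ev in rec$stimulation_events) {
    if (!is.null(crit$frequency) && ev$frequency_hz != crit$frequency) next
    if (!is.null(crit$response_category) &&
        ev$response_category != crit$response_category) next
    if (!is.null(crit$classification) &&
        !crit$classification %in% ev$classifications) next
    la <- labs[[col]][labs$electrode == ev$electrode & labs$contact == ev$contact_a]
    lb <- labs[[col]][labs$electrode == ev$electrode & labs$contact == ev$contact_b]
    ina <- length(la) && la == crit$name
    inb <- length(lb) && lb == crit$name
    if ((both && ina && inb) || (!both && (ina || inb))) return(TRUE)
  }
  FALSE
}

# ---- group export -----------------------------------------------------------

#' Mirror left-hemisphere MNI coordinates onto the right
#'
#' Points with x < 0 get their x coordinate negated; all other points are
#' unchanged. Used to pool both hemispheres on one glass-brain side.
#'
#' @param coords Length-3 vector or n x 3 matrix of MNI mm points.
#' @export
flip_left_right <- function(coords) {
  m <- if (is.matrix(coords)) coords else matrix(coords, ncol = 3L)
  m[, 1L] <- ifelse(m[, 1L] < 0, -m[, 1L], m[, 1L])
  if (is.matrix(coords)) m else drop(m)
}

#' Export the pooled contact cloud of a cohort
#'
#' One row per contact with MNI coordinates, its parcel label in `atlas`,
#' tissue class and a stimulation summary, pooled across the selected
#' patients — the flat table consumed by [qc_report()] and by external
#' glass-brain plotting. Patients without MNI coordinates are skipped and
#' listed in the `patients_without_mni` attribute.
#'
#' @param store A `cohort_store`.
#' @param atlas Atlas name whose labels populate the `parcel` column.
#' @param parcel Optional parcel name filter.
#' @param patients Optional character vector of patient ids.
#' @param flip Mirror left-side contacts to the right (default FALSE).
#' @return data.frame (patient_id, electrode, contact, mni_x, mni_y, mni_z,
#'   parcel, tissue, stim_summary), deterministically ordered.
#' @export
export_group_cloud <- function(store, atlas, parcel = NULL, patients = NULL,
                               flip = FALSE) {
  stopifnot(inherits(store, "cohort_store"))
  ids <- sort(if (is.null(patients)) names(store$patients) else patients)
  rows <- list()
  nomni <- character(0)
  for (id in ids) {
    rec <- store$patients[[id]]
    if (is.null(rec)) stop("export_group_cloud: unknown patient '", id, "'",
                           call. = FALSE)
    if (is.null(rec$mni_coords) || nrow(rec$mni_coords) == 0L) {
      nomni <- c(nomni, id); next
    }
    labs <- rec$contact_labels
    col <- paste0(atlas, "_name")
    mni <- rec$mni_coords[order(rec$mni_coords$electrode,
                                rec$mni_coords$contact), , drop = FALSE]
    key <- paste(mni$electrode, mni$contact)
    pn <- if (!is.null(labs) && col %in% names(labs))
      labs[[col]][match(key, paste(labs$electrode, labs$contact))] else
        rep(NA_character_, nrow(mni))
    tis <- if (!is.null(labs) && "tissue" %in% names(labs))
      labs$tissue[match(key, paste(labs$electrode, labs$contact))] else
        rep(NA_character_, nrow(mni))
    stim <- vapply(seq_len(nrow(mni)), function(i) {
      evs <- Filter(function(ev) ev$electrode == mni$electrode[i] &&
                      mni$contact[i] %in% c(ev$contact_a, ev$contact_b),
                    rec$stimulation_events)
      if (!length(evs)) return("")
      paste(sort(unique(vapply(evs, `[[`, "", "response_category"))),
            collapse = ";")
    }, "")
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = id, electrode = mni$electrode, contact = mni$contact,
      mni_x = mni$x, mni_y = mni$y, mni_z = mni$z,
      parcel = ifelse(is.na(pn), "unlabeled", pn),
      tissue = ifelse(is.na(tis), "unlabeled", tis),
      stim_summary = stim, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), electrode = character(0),
               contact = integer(0), mni_x = numeric(0), mni_y = numeric(0),
               mni_z = numeric(0), parcel = character(0),
               tissue = character(0), stim_summary = character(0))
  if (length(nomni))
    warning("export_group_cloud: no MNI coordinates for patient(s): ",
            paste(nomni, collapse = ", "))
  if (!is.null(parcel)) out <- out[out$parcel == parcel, , drop = FALSE]
  if (flip && nrow(out))
    out[, c("mni_x", "mni_y", "mni_z")] <-
      flip_left_right(as.matrix(out[, c("mni_x", "mni_y", "mni_z")]))
  rownames(out) <- NULL
  attr(out, "patients_without_mni") <- nomni
  out
}
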