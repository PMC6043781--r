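# Parametric depth-electrode models and contact placement along a two-point
# trajectory (deep tip + any shaft point), as clinicians mark them on
# post-implantation images.

#' Construct a parametric electrode model
#'
#' A depth electrode is described by ordered segments of identical contacts:
#' each segment has `n_contacts` cylindrical contacts of length
#' `contact_length_mm`, separated by `gap_after_mm` of insulation; the same
#' gap also separates the segment from the next one, which encodes
#' grouped-contact layouts (e.g. 3 groups of 5) without per-manufacturer
#' code. `tip_offset_mm` shifts the first contact away from the geometric tip
#' (default 0: contact 1 starts exactly at the tip).
#'
#' @param model_name Model identifier string.
#' @param segments data.frame (or list coercible to one) with columns
#'   `n_contacts`, `contact_length_mm`, `gap_after_mm`.
#' @param diameter_mm Shaft diameter in mm.
#' @param tip_offset_mm Distance from tip to the start of contact 1, mm.
#' @return An `electrode_model` object.
#' @export
electrode_model <- function(model_name, segments, diameter_mm = 0.8,
                            tip_offset_mm = 0) {
  segments <- as.data.frame(segments)
  need <- c("n_contacts", "contact_length_mm", "gap_after_mm")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop(sprintf("electrode_model '%s': segments missing field(s) %s",
                 model_name, paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(segments) < 1L)
    stop(sprintf("electrode_model '%s': at least one segment required",
                 model_name), call. = FALSE)
  chk <- function(ok, field) if (!all(ok))
    stop(sprintf("electrode_model '%s': invalid %s", model_name, field),
         call. = FALSE)
  chk(is.finite(segments$n_contacts) & segments$n_contacts >= 1 &
        segments$n_contacts == round(segments$n_contacts), "n_contacts")
  chk(is.finite(segments$contact_length_mm) & segments$contact_length_mm > 0,
      "contact_length_mm")
  chk(is.finite(segments$gap_after_mm) & segments$gap_after_mm >= 0,
      "gap_after_mm")
  if (!is.finite(diameter_mm) || diameter_mm <= 0)
    stop(sprintf("electrode_model '%s': invalid diameter_mm", model_name),
         call. = FALSE)
  if (!is.finite(tip_offset_mm) || tip_offset_mm < 0)
    stop(sprintf("electrode_model '%s': invalid tip_offset_mm", model_name),
         call. = FALSE)
  structure(list(model_name = as.character(model_name),
                 segments = segments[need],
                 diameter_mm = diameter_mm,
                 tip_offset_mm = tip_offset_mm),
            class = "electrode_model")
}

#' @export
print.electrode_model <- function(x, ...) {
  cat(sprintf("<electrode_model %s: %d contacts, length %.2f mm>\n",
              x$model_name, n_contacts(x), electrode_length(x)))
  invisible(x)
}

#' Total number of contacts of a model
#' @param model An `electrode_model`.
#' @export
n_contacts <- function(model) sum(model$segments$n_contacts)

# Distance from the tip-side start of the contact array to the start of each
# contact; one entry per contact, tip-first. Offset 1 is 0.
contact_start_offsets <- function(model) {
  offs <- numeric(0)
  pos <- 0
  for (s in seq_len(nrow(model$segments))) {
    seg <- model$segments[s, ]
    for (c in seq_len(seg$n_contacts)) {
      offs <- c(offs, pos)
      pos <- pos + seg$contact_length_mm + seg$gap_after_mm
    }
  }
  offs
}

contact_lengths <- function(model) {
  rep(model$segments$contact_length_mm, model$segments$n_contacts)
}

#' Physical length of the contact-bearing part of an electrode
#'
#' Sum of all contact lengths and inter-contact gaps, excluding the gap after
#' the final contact and any tip offset.
#'
#' @param model An `electrode_model`.
#' @return Length in mm.
#' @export
electrode_length <- function(model) {
  offs <- contact_start_offsets(model)
  lens <- contact_lengths(model)
  offs[length(offs)] + lens[length(lens)]
}

#' Place an electrode model along a two-point trajectory
#'
#' The trajectory is given by the electrode tip (its deepest point) and any
#' other point along the shaft; contacts are laid out from the tip toward the
#' shaft point. Contact i's center is
#' `tip + u * (tip_offset + offset_i + L_i / 2)` where `u` is the unit vector
#' from tip to shaft point and `offset_i` the cumulative length of preceding
#' contacts and gaps (`offset_1 = 0`). Contacts are numbered from 1 at the
#' tip, matching clinical convention (contact 1 = deepest).
#'
#' @param model An `electrode_model`.
#' @param tip_point Length-3 world mm: deepest end of the electrode.
#' @param shaft_point Length-3 world mm: any other point along the shaft,
#'   superficial to the tip.
#' @param name Electrode name (e.g. `"Q'"`).
#' @return A `placed_electrode` with `contact_centers` (n x 3 matrix, row 1 =
#'   deepest contact).
#' @export
place_electrode <- function(model, tip_point, shaft_point, name) {
  stopifnot(inherits(model, "electrode_model"))
  tip <- as.numeric(tip_point); shaft <- as.numeric(shaft_point)
  if (length(tip) != 3L || length(shaft) != 3L)
    stop("place_electrode: tip and shaft points must be length-3", call. = FALSE)
  d <- shaft - tip
  nd <- sqrt(sum(d^2))
  if (nd <= 1e-6)
    stop("place_electrode: degenerate trajectory (tip and shaft points coincide)",
         call. = FALSE)
  u <- d / nd
  centers_1d <- model$tip_offset_mm + contact_start_offsets(model) +
    contact_lengths(model) / 2
  centers <- sweep(outer(centers_1d, u), 2L, tip, `+`)
  colnames(centers) <- c("x", "y", "z")
  structure(list(electrode_name = as.character(name), model = model,
                 tip_point = tip, shaft_point = shaft,
                 contact_centers = centers),
            class = "placed_electrode")
}

#' @export
print.placed_electrode <- function(x, ...) {
  cat(sprintf("<placed_electrode %s (%s): %d contacts, tip (%.1f, %.1f, %.1f)>\n",
              x$electrode_name, x$model$model_name, nrow(x$contact_centers),
              x$tip_point[1], x$tip_point[2], x$tip_point[3]))
  invisible(x)
}

#' Load an electrode model catalog from JSON
#'
#' The catalog is a JSON array of objects
#' `{model_name, diameter_mm, segments: [{n_contacts, contact_length_mm,
#' gap_after_mm}], tip_offset_mm}`. Every model is validated against the
#' [electrode_model()] invariants; validation errors name the model and
#' field.
#'
#' @param path JSON file; defaults to the bundled illustrative catalog.
#' @return Named list of `electrode_model` objects.
#' @export
load_model_catalog <- function(path = system.file("extdata",
                                                  "electrode_models.json",
                                                  package = "seegloc")) {
  if (!file.exists(path))
    stop("load_model_catalog: file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw) || !length(raw))
    stop("load_model_catalog: catalog must be a non-empty JSON array",
         call. = FALSE)
  models <- lapply(raw, function(m) {
    nm <- if (is.null(m$model_name)) "<unnamed>" else m$model_name
    if (is.null(m$segments))
      stop(sprintf("electrode_model '%s': missing field segments", nm),
           call. = FALSE)
    segs <- do.call(rbind, lapply(m$segments, function(s) {
      for (f in c("n_contacts", "contact_length_mm", "gap_after_mm"))
        if (is.null(s[[f]]))
          stop(sprintf("electrode_model '%s': segment missing field %s", nm, f),
               call. = FALSE)
      data.frame(n_contacts = s$n_contacts,
                 contact_length_mm = s$contact_length_mm,
                 gap_after_mm = s$gap_after_mm)
    }))
    electrode_model(nm, segs,
                    diameter_mm = if (is.null(m$diameter_mm)) 0.8 else m$diameter_mm,
                    tip_offset_mm = if (is.null(m$tip_offset_mm)) 0 else m$tip_offset_mm)
  })
  names(models) <- vapply(models, `[[`, "", "model_name")
  if (anyDuplicated(names(models)))
    stop("load_model_catalog: duplicate model names", call. = FALSE)
  models
}

#' Serialize placed electrodes to a JSON file
#'
#' The full model definition is embedded with every electrode, so the file
#' is self-contained.
#'
#' @param electrodes List of `placed_electrode` objects.
#' @param path Output path.
#' @export
write_electrodes <- function(electrodes, path) {
  obj <- lapply(electrodes, function(e) list(
    electrode_name = e$electrode_name,
    model = list(model_name = e$model$model_name,
                 diameter_mm = e$model$diameter_mm,
                 tip_offset_mm = e$model$tip_offset_mm,
                 segments = e$model$segments),
    tip_point = e$tip_point,
    shaft_point = e$shaft_point,
    contact_centers = unname(apply(e$contact_centers, 1L, as.list,
                                   simplify = FALSE))
  ))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read placed electrodes from a JSON file
#'
#' Electrodes are re-placed from their stored trajectory and embedded model
#' definition (or a named catalog model for files that only carry a model
#' name), so geometry always derives from the model, never from stored
#' coordinates.
#'
#' @param path JSON file written by [write_electrodes()].
#' @param catalog Model catalog used to resolve name-only references.
#' @export
read_electrodes <- function(path, catalog = load_model_catalog()) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(e) {
    mdl <- if (!is.null(e$model)) {
      segs <- do.call(rbind, lapply(e$model$segments, as.data.frame))
      electrode_model(e$model$model_name, segs,
                      diameter_mm = e$model$diameter_mm,
                      tip_offset_mm = e$model$tip_offset_mm)
    } else catalog[[e$model_name]]
    if (is.null(mdl))
      stop("read_electrodes: unknown model '", e$model_name, "'", call. = FALSE)
    place_electrode(mdl, unlist(e$tip_point), unlist(e$shaft_point),
                    e$electrode_name)
  })
}
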