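# Patient records, persistence, stimulation import and cohort queries.

toy_patient <- function(id = "pt01", nc = 5L, parcel = "p01",
                        resected = NULL, engel = "I", center = "C1",
                        year = 2015L) {
  m <- electrode_model("T", data.frame(n_contacts = nc, contact_length_mm = 2,
                                       gap_after_mm = 1.5))
  el <- place_electrode(m, c(0, 0, 0), c(0, 0, 40), "Q'")
  labs <- data.frame(electrode = "Q'", contact = seq_len(nc),
                     x = 0, y = 0, z = (seq_len(nc) - 1) * 3.5 + 1,
                     toy_label = 1L, toy_name = parcel, tissue = "GM",
                     in_resection = FALSE, stringsAsFactors = FALSE)
  overlap <- if (!is.null(resected))
    structure(list(total_volume_mm3 = 500,
                   per_parcel = data.frame(atlas = "toy", label = 1L,
                                           name = resected,
                                           parcel_voxels = 1000L,
                                           resected_voxels = 300L,
                                           percent = 30,
                                           stringsAsFactors = FALSE),
                   brain_shift_unreliable = TRUE),
              class = "overlap_report")
  patient_record(id, center, year, engel, electrodes = list(el),
                 contact_labels = labs, overlap_report = overlap,
                 stimulation_events = list(
                   stimulation_event("Q'", 1L, 2L, 50, "seizure_like",
                                     classifications = "motor",
                                     intensity_ma = 2)),
                 mni_coords = labs[, c("electrode", "contact", "x", "y", "z")])
}

test_that("records validate their invariants", {
  expect_error(patient_record("", "C", 2015), "non-empty")
  expect_error(patient_record("p", "C", 15), "4-digit")
  expect_error(patient_record("p", "C", 2015, engel_class = "V"), "engel")
  expect_error(stimulation_event("A", 1, 3, 50, "no_response"), "adjacent")
  expect_error(stimulation_event("A", 1, 2, 20, "no_response"), "1 or 50")
  expect_error(stimulation_event("A", 1, 2, 50, "weird"), "response_category")
  expect_error(stimulation_event("A", 1, 2, 50, "not_stimulated",
                                 classifications = "motor"),
               "not_stimulated")
  # stimulation referencing a non-existent contact
  m <- electrode_model("T", data.frame(n_contacts = 5, contact_length_mm = 2,
                                       gap_after_mm = 1.5))
  el <- place_electrode(m, c(0, 0, 0), c(0, 0, 40), "Q'")
  expect_error(
    patient_record("p", "C", 2015, electrodes = list(el),
                   stimulation_events = list(
                     stimulation_event("Q'", 98L, 99L, 50, "no_response"))),
    "99")
})

test_that("store roundtrips and save/load/save is byte-stable", {
  store <- cohort_store()
  store <- add_patient(store, toy_patient("a01", resected = "p01"))
  store <- add_patient(store, toy_patient("a02", engel = "III"))
  expect_error(add_patient(store, toy_patient("a01")), "duplicate")
  expect_equal(n_patients(add_patient(store, toy_patient("a01"),
                                      overwrite = TRUE)), 2L)

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_store(store, f1)
  back <- load_store(f1)
  expect_equal(n_patients(back), 2L)
  r <- back$patients$a01
  expect_equal(r$center, "C1")
  expect_equal(r$year, 2015L)
  expect_equal(r$engel_class, "I")
  expect_equal(r$electrodes[[1]]$contact_centers,
               store$patients$a01$electrodes[[1]]$contact_centers)
  expect_equal(r$contact_labels$toy_name,
               store$patients$a01$contact_labels$toy_name)
  expect_equal(r$overlap_report$per_parcel$percent, 30)
  expect_equal(r$stimulation_events[[1]]$classifications, "motor")
  expect_equal(r$mni_coords$z, store$patients$a01$mni_coords$z)
  save_store(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("stimulation tables import with row-level validation", {
  pat <- toy_patient()
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bipole,frequency_hz,intensity_ma,response_category,classifications",
               "Q'1-Q'2,50,2,seizure_like,motor;emotional",
               "Q'2-Q'3,1,1,no_response,",
               "Q'4-Q'5,50,3,response_non_epileptic,sensory"), csv)
  evs <- import_stim_table(csv, pat)
  expect_length(evs, 3L)
  expect_equal(evs[[1]]$classifications, c("emotional", "motor"))
  expect_equal(evs[[2]]$frequency_hz, 1)

  bad1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bipole,frequency_hz,intensity_ma,response_category,classifications",
               "Q'1-Q'2,20,2,no_response,"), bad1)
  expect_error(import_stim_table(bad1, pat), "row 1.*1 or 50")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bipole,frequency_hz,intensity_ma,response_category,classifications",
               "Q'1-Q'2,50,2,no_response,",
               "Q'98-Q'99,50,2,no_response,"), bad2)
  expect_error(import_stim_table(bad2, pat), "row 2.*99")
})

test_that("queries are exact conjunctions matching a brute-force filter", {
  store <- cohort_store()
  store <- add_patient(store, toy_patient("A", parcel = "R_ICC",
                                          resected = "R_ICC"))
  store <- add_patient(store, toy_patient("B", parcel = "R_ICC"))
  store <- add_patient(store, toy_patient("C", parcel = "L_ICC",
                                          resected = "R_ICC", engel = "II"))
  # contact in R_ICC AND R_ICC at least partially resected -> only A
  got <- query(store, contact_in_parcel = list(atlas = "toy", name = "R_ICC"),
               resected_parcel = list(atlas = "toy", name = "R_ICC"))
  expect_equal(got, "A")
  expect_equal(query(store), c("A", "B", "C"))
  expect_error(query(store, contact_in_parcel = list(atlas = "nope",
                                                     name = "R_ICC")),
               "unknown atlas")
  expect_error(query(store, contact_in_parcel = list(atlas = "toy",
                                                     name = "nope")),
               "unknown parcel")
  expect_error(query(store, engel_class = "VII"), "Engel")

  # randomized criteria against the brute-force oracle on a generated cohort
  coh <- make_cohort(small_cohort_spec(seed = 7L, n_patients = 8L))
  set.seed(31)
  parcels <- unique(coh$truth$labels$synthatlas_name)
  parcels <- parcels[parcels != "unlabeled"]
  for (i in 1:40) {
    crit <- list()
    if (runif(1) < 0.4) crit$center <- sample(c("CenterA", "CenterB",
                                                "CenterC"), 1)
    if (runif(1) < 0.4) crit$year_range <- sort(sample(2008:2020, 2))
    if (runif(1) < 0.4) crit$engel_class <- sample(c("I", "II", "III"),
                                                   sample(1:2, 1))
    if (runif(1) < 0.5) crit$contact_in_parcel <-
        list(atlas = "synthatlas", name = sample(parcels, 1))
    if (runif(1) < 0.3) crit$resected_parcel <-
        list(atlas = "synthatlas", name = sample(coh$lookup$name, 1))
    got <- tryCatch(do.call(query, c(list(coh$store), crit)),
                    error = function(e) e)
    if (inherits(got, "error")) {
      # only the unknown-parcel validation may reject a random criterion
      expect_match(conditionMessage(got), "unknown parcel")
    } else {
      expect_identical(got, do.call(oracle_query, c(list(coh$store), crit)))
    }
  }
})

test_that("stimulated-parcel criterion resolves through bipole contact labels", {
  pat <- toy_patient("S1", parcel = "p01")
  store <- add_patient(cohort_store(), pat)
  expect_equal(query(store, stimulated_parcel = list(
    atlas = "toy", name = "p01", frequency = 50,
    response_category = "seizure_like", classification = "motor")), "S1")
  expect_equal(query(store, stimulated_parcel = list(
    atlas = "toy", name = "p01", frequency = 1)), character(0))
})

test_that("left/right flip mirrors only the left half-space and is idempotent", {
  expect_equal(flip_left_right(c(-42, 10, 5)), c(42, 10, 5))
  expect_equal(flip_left_right(c(42, 10, 5)), c(42, 10, 5))
  expect_equal(flip_left_right(c(0, 0, 0)), c(0, 0, 0))
  set.seed(2)
  pts <- matrix(rnorm(60, sd = 30), ncol = 3)
  once <- flip_left_right(pts)
  expect_true(all(once[, 1] >= 0))
  expect_identical(flip_left_right(once), once)
  expect_equal(abs(pts[, 1]), once[, 1])
})

test_that("group cloud export is deterministic and complete", {
  pat <- toy_patient("G1")
  store <- add_patient(cohort_store(), pat)
  cl <- export_group_cloud(store, "toy")
  expect_equal(nrow(cl), 5L)  # one electrode, five contacts
  expect_equal(cl$parcel, rep("p01", 5))
  expect_match(cl$stim_summary[1], "seizure_like")
  cl2 <- export_group_cloud(store, "toy")
  expect_identical(cl, cl2)
  # patients without MNI coordinates are reported, not dropped silently
  nom <- patient_record("G2", "C1", 2015)
  store2 <- add_patient(store, nom)
  expect_warning(cl3 <- export_group_cloud(store2, "toy"), "G2")
  expect_equal(attr(cl3, "patients_without_mni"), "G2")
})
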