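# Sphere neighbourhoods and per-contact labeling.

test_that("sphere_voxels counts lattice points exactly", {
  vol <- volume3d(array(0, dim = c(21, 21, 21)), diag(4), "atlas")
  ctr <- c(10, 10, 10)  # a voxel center on a 1 mm grid
  idx <- sphere_voxels(ctr, vol, 3)
  expect_equal(nrow(idx), 123L)  # lattice points with |v|^2 <= 9
  expect_equal(nrow(sphere_voxels(ctr, vol, 0.4)), 1L)
  expect_equal(nrow(sphere_voxels(c(500, 0, 0), vol, 3)), 0L)
})

test_that("sphere_voxels equals the per-voxel oracle on anisotropic grids", {
  set.seed(5)
  for (i in 1:25) {
    aff <- rand_affine(rotate = i %% 2 == 0)
    vol <- volume3d(array(0, dim = c(9, 8, 7)), aff, "atlas")
    ctr <- as.numeric(voxel_to_world(runif(3, -1, 8), vol))
    r <- runif(1, 0.5, 4)
    got <- sphere_voxels(ctr, vol, r)
    exp <- oracle_sphere(ctr, vol, r)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(exp)),
                 ignore_attr = TRUE)
  }
})

test_that("atlas labeling is a gray-matter-restricted majority vote", {
  aff <- diag(4)
  d <- c(11, 11, 11)
  uni <- volume3d(array(7L, dim = d), aff, "atlas")
  lk <- label_lookup(data.frame(label = c(3, 5, 7, 8),
                                name = c("a", "b", "c", "w"),
                                hemisphere = "none", atlas = "toy"),
                     cortical = TRUE)
  expect_equal(label_atlas(c(5, 5, 5), uni, lk)$label, 7L)

  # sphere dominated by white matter: the few gray-matter parcel voxels win
  atlas <- array(0L, dim = d)
  tissue <- array(3L, dim = d)          # all white matter
  gm <- rbind(c(5, 5, 5), c(6, 5, 5), c(4, 5, 5), c(5, 6, 5), c(5, 4, 5))
  for (r in seq_len(nrow(gm))) {
    atlas[gm[r, 1] + 1, gm[r, 2] + 1, gm[r, 3] + 1] <- 3L
    tissue[gm[r, 1] + 1, gm[r, 2] + 1, gm[r, 3] + 1] <- 2L
  }
  # white-matter voxels even carry a competing label that must be ignored
  wm_lab <- array(8L, dim = d); wm_lab[atlas == 3L] <- 3L
  av <- volume3d(wm_lab, aff, "atlas")
  tv <- volume3d(tissue, aff, "tissue")
  res <- label_atlas(c(5, 5, 5), av, lk, tissue = tv)
  expect_equal(res$label, 3L)
  expect_equal(res$name, "a")
  # without the tissue restriction the white-matter label dominates
  expect_equal(label_atlas(c(5, 5, 5), av, lk)$label, 8L)
  # and an empty candidate set yields unlabeled
  res0 <- label_atlas(c(5, 5, 5), volume3d(array(0L, d), aff, "atlas"), lk,
                      tissue = tv)
  expect_equal(res0$label, 0L)
  expect_equal(res0$name, "unlabeled")
})

test_that("exact ties break toward the smallest label id", {
  aff <- diag(4); d <- c(9, 9, 9)
  atlas <- array(0L, dim = d)
  atlas[5, 5, 5] <- 5L; atlas[6, 5, 5] <- 3L   # one voxel each inside r=1.2
  av <- volume3d(atlas, aff, "atlas")
  lk <- simple_lookup(5)
  expect_equal(label_atlas(c(4.5, 4, 4), av, lk, radius_mm = 1.2)$label, 3L)
})

test_that("tissue labeling is a majority vote with GM>WM>CSF tie-break", {
  aff <- diag(4); d <- c(9, 9, 9)
  expect_equal(label_tissue(c(4, 4, 4),
                            volume3d(array(3L, d), aff, "tissue")), "WM")
  # 60/40 majority
  tis <- array(0L, dim = d)
  tis[1:5, , ] <- 2L; tis[6:9, , ] <- 3L
  expect_equal(label_tissue(c(4, 4, 4), volume3d(tis, aff, "tissue"),
                            radius_mm = 8), "GM")
  # random volumes vs counting oracle
  set.seed(9)
  for (i in 1:40) {
    tv <- rand_volume(c(8, 8, 8), "tissue", affine = rand_affine(FALSE))
    ctr <- as.numeric(voxel_to_world(runif(3, 0, 7), tv))
    expect_equal(label_tissue(ctr, tv, 2.5), oracle_label_tissue(ctr, tv, 2.5))
  }
})

test_that("statmap means average the sphere and handle degenerate cases", {
  aff <- diag(4); d <- c(9, 9, 9)
  expect_equal(statmap_mean(c(4, 4, 4),
                            volume3d(array(2.5, d), aff, "statmap")), 2.5)
  sm <- array(0, dim = d); sm[5, 5, 5] <- 10
  # radius 1 on a 1 mm grid: the 7-voxel cross
  expect_equal(statmap_mean(c(4, 4, 4), volume3d(sm, aff, "statmap"),
                            radius_mm = 1), 10 / 7)
  expect_warning(
    out <- statmap_mean(c(100, 100, 100), volume3d(sm, aff, "statmap")),
    "empty sphere")
  expect_true(is.nan(out))
  # NaN voxels are excluded from the mean
  sm2 <- array(1, dim = d); sm2[5, 5, 5] <- NaN
  expect_equal(statmap_mean(c(4, 4, 4), volume3d(sm2, aff, "statmap"),
                            radius_mm = 1), 1)
})

test_that("resection membership uses the containing voxel", {
  aff <- diag(4); d <- c(9, 9, 9)
  m <- array(0, dim = d); m[3:6, 3:6, 3:6] <- 1
  mv <- volume3d(m, aff, "mask")
  expect_true(resection_flag(c(4, 4, 4), mv))
  expect_false(resection_flag(c(0, 0, 0), mv))
  expect_false(resection_flag(c(-50, 0, 0), mv))
  expect_false(resection_flag(c(4, 4, 4),
                              volume3d(array(0, d), aff, "mask")))
  # boundary: nearest-voxel lookup decides
  expect_identical(resection_flag(c(2.4, 4, 4), mv), m[3, 5, 5] == 1)
  expect_identical(resection_flag(c(2.6, 4, 4), mv), m[4, 5, 5] == 1)
})

test_that("majority labeling never returns a label without GM support and is
           monotone under parcel growth", {
  set.seed(21)
  lk <- simple_lookup(4, cortical = TRUE)
  for (i in 1:30) {
    av <- rand_volume(c(8, 8, 8), "atlas", nlab = 4)
    tv <- rand_volume(c(8, 8, 8), "tissue")
    ctr <- as.numeric(voxel_to_world(runif(3, 0, 7), av))
    got <- label_atlas(ctr, av, lk, tissue = tv)$label
    expect_equal(got, oracle_label_atlas(ctr, av, tv, 3, TRUE))
    if (got != 0L) {
      idx <- sphere_voxels(ctr, av, 3)
      has_gm <- any(apply(idx, 1, function(v)
        av$data[v[1] + 1, v[2] + 1, v[3] + 1] == got &&
          tv$data[v[1] + 1, v[2] + 1, v[3] + 1] == 2))
      expect_true(has_gm)
    }
  }
  # monotonicity: growing a uniform parcel around the contact keeps its label
  d <- c(13, 13, 13); aff <- diag(4)
  for (rad in 2:5) {
    atlas <- array(0L, dim = d)
    for (i in 0:12) for (j in 0:12) for (k in 0:12)
      if (sum((c(i, j, k) - 6)^2) <= rad^2) atlas[i + 1, j + 1, k + 1] <- 2L
    got <- label_atlas(c(6, 6, 6), volume3d(atlas, aff, "atlas"),
                       simple_lookup(4))$label
    expect_equal(got, 2L)
  }
})

test_that("label_all produces one deterministic row per contact", {
  spec <- fixture_spec(grid_shape = c(32L, 32L, 32L), seed = 2L,
                       n_parcels = 8L)
  h <- make_head(spec)
  a <- make_atlas(h$tissue, 8L)
  m <- electrode_model("T5", data.frame(n_contacts = 5, contact_length_mm = 2,
                                        gap_after_mm = 1.5))
  els <- list(place_electrode(m, c(-10, 0, 0), c(20, 4, 2), "A"),
              place_electrode(m, c(0, -10, 0), c(3, 20, -2), "B"))
  sm <- volume3d(array(1.5, dim = dim(h$tissue$data)), h$tissue$affine,
                 "statmap")
  labs <- label_all(els, atlases = list(synthatlas = list(volume = a$atlas,
                                                          lookup = a$lookup)),
                    tissue = h$tissue, resection = h$mask,
                    statmaps = list(epi = sm))
  expect_equal(nrow(labs), 10L)
  expect_named(labs, c("electrode", "contact", "x", "y", "z",
                       "synthatlas_label", "synthatlas_name", "tissue",
                       "in_resection", "stat_epi"))
  expect_equal(labs$stat_epi, rep(1.5, 10))

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_contact_labels(labs, f1)
  write_contact_labels(label_all(
    els, atlases = list(synthatlas = list(volume = a$atlas,
                                          lookup = a$lookup)),
    tissue = h$tissue, resection = h$mask, statmaps = list(epi = sm)), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(label_all(c(els, els[1]), atlases = list()), "duplicate")
  small <- volume3d(array(0L, dim = c(4, 4, 4)), diag(4), "tissue")
  expect_error(
    label_all(els, atlases = list(s = list(volume = a$atlas,
                                           lookup = a$lookup)),
              tissue = small),
    "share the pre-implantation grid")
})
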