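test_that("blank stain maps give zero detections", {
  img <- calibrated_image(array(255, dim = c(64, 64, 3)), 0.5)
  st <- separate_stains(img)
  det <- detect_nuclei(st)
  expect_equal(nrow(det$table), 0)
  expect_s3_class(det, "cell_detections")
})

test_that("well-separated planted nuclei are each detected within 2 px", {
  # no crypts: the whole tissue blob is lamina propria with room to spare
  probe <- generate_tissue_image(small_spec(seed = 10, n_crypts = 0))
  lp_area <- probe$truth$compartments$areas_mm2[["lamina_propria"]]
  g <- generate_tissue_image(small_spec(
    seed = 10, n_crypts = 0,
    cell_density = c(epithelium = 0, subepithelial = 0,
                     lamina_propria = 20 / lp_area),
    min_separation_um = 12
  ))
  expect_equal(nrow(g$truth$cells), 20)
  st <- separate_stains(g$image)
  det <- detect_nuclei(st)
  expect_equal(nrow(det$table), 20)
  m <- match_detections(cbind(det$table$x, det$table$y),
                        cbind(g$truth$cells$x, g$truth$cells$y), tol = 2)
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["precision"]), 1)
})

test_that("two nuclei three radii apart remain two detections", {
  # plant two 3 um nuclei 9 um apart on a plain background
  h <- w <- 96; mpp <- 0.5
  hema <- matrix(0, h, w)
  for (cx in c(39, 57)) {   # 18 px = 9 um apart
    dd <- sqrt(outer((1:h - 48)^2, (1:w - cx)^2, "+"))
    hema[dd <= 6] <- 0.8
  }
  rgb <- render_stains(list(hema, matrix(0, h, w)), hdab_stain_matrix())
  st <- separate_stains(calibrated_image(rgb, mpp))
  det <- detect_nuclei(st)
  expect_equal(nrow(det$table), 2)
})

test_that("the area filter applies inclusive bounds at the reference scale", {
  s <- detection_settings()
  fake <- detections_from_truth(
    data.frame(x = c(5, 15, 25, 35) + 0.5, y = rep(5.5, 4),
               area_um2 = c(124, 125, 3000, 3001) * s$requested_pixel_size^2,
               class = "negative"),
    h = 48, w = 48, mpp = 0.5
  )
  out <- filter_by_area(fake, s)
  expect_equal(out$table$area_px2_ref, c(125, 3000))
  # removed ids are erased from the label raster too
  expect_false(any(out$labels %in% c(1L, 4L)))
  # pure function: idempotent, output subset of input
  again <- filter_by_area(out, s)
  expect_identical(again$table, out$table)
})

test_that("area bounds translate to physical units", {
  expect_equal(125 * 0.225^2, 6.328125)
  s <- detection_settings()
  expect_equal(s$min_nucleus_area * s$requested_pixel_size^2, 6.328125)
})

test_that("zero expansion keeps the cell region equal to the nucleus", {
  g <- generate_tissue_image(small_spec(seed = 12))
  st <- separate_stains(g$image)
  det <- filter_by_area(detect_nuclei(st))
  s0 <- detection_settings(cell_expansion_um = 0)
  out <- expand_cells(det, st, s0)
  expect_identical(out$cell_labels, out$labels)
})

test_that("an isolated nucleus expands to the analytic disk area", {
  h <- w <- 120; mpp <- 0.25
  hema <- matrix(0, h, w)
  dd <- sqrt(outer((1:h - 60)^2, (1:w - 60)^2, "+"))
  hema[dd <= 3 / mpp] <- 0.8   # 3 um radius
  rgb <- render_stains(list(hema, matrix(0, h, w)), hdab_stain_matrix())
  st <- separate_stains(calibrated_image(rgb, mpp))
  det <- expand_cells(filter_by_area(detect_nuclei(st)), st)
  expect_equal(nrow(det$table), 1)
  cell_area_um2 <- sum(det$cell_labels == det$table$id[1]) * mpp^2
  expect_equal(cell_area_um2, pi * (3 + 1.5)^2, tolerance = 0.05)
})

test_that("overlapping expansions are split at the nearest-nucleus midline", {
  h <- w <- 96; mpp <- 0.5
  hema <- matrix(0, h, w)
  centers <- c(42, 54)          # 6 um apart, expansion 1.5 um each side
  for (cx in centers) {
    dd <- sqrt(outer((1:h - 48)^2, (1:w - cx)^2, "+"))
    hema[dd <= 5] <- 0.8
  }
  rgb <- render_stains(list(hema, matrix(0, h, w)), hdab_stain_matrix())
  st <- separate_stains(calibrated_image(rgb, mpp))
  det <- expand_cells(filter_by_area(detect_nuclei(st)), st)
  expect_equal(nrow(det$table), 2)
  cl <- det$cell_labels
  # regions are disjoint by construction of the label raster; verify the
  # midline rule against brute-force nearest-nucleus distances
  nuc <- det$labels
  d1 <- brute_force_distance(nuc == det$table$id[1])
  d2 <- brute_force_distance(nuc == det$table$id[2])
  own1 <- cl == det$table$id[1] & nuc == 0
  own2 <- cl == det$table$id[2] & nuc == 0
  expect_true(all(d1[own1] <= d2[own1] + 1e-9))
  expect_true(all(d2[own2] <= d1[own2] + 1e-9))
})

test_that("detection is deterministic for fixed inputs", {
  g <- generate_tissue_image(small_spec(seed = 13, artefact_density = 40))
  st <- separate_stains(g$image)
  d1 <- expand_cells(filter_by_area(detect_nuclei(st)), st)
  d2 <- expand_cells(filter_by_area(detect_nuclei(st)), st)
  expect_identical(d1$table, d2$table)
  expect_identical(d1$cell_labels, d2$cell_labels)
})
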