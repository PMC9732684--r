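test_that("expansion by zero distance is the identity", {
  g <- generate_tissue_image(small_spec(seed = 1))
  e <- expand_epithelium(g$truth$epithelium_mask, 0)
  expect_identical(e$mask, g$truth$epithelium_mask$mask)
  expect_equal(e$role, "expanded_epithelium")
})

test_that("an empty mask expands to an empty mask", {
  m <- binary_mask(matrix(FALSE, 20, 20), 0.5, "epithelium")
  expect_false(any(expand_epithelium(m, 5)$mask))
})

test_that("negative distances are rejected", {
  m <- binary_mask(matrix(FALSE, 5, 5), 0.5, "epithelium")
  expect_error(expand_epithelium(m, -1), "non-negative")
})

test_that("single-pixel expansion matches the brute-force distance oracle", {
  m <- matrix(FALSE, 41, 41); m[21, 21] <- TRUE
  e <- expand_epithelium(binary_mask(m, 0.5, "epithelium"), 5)
  oracle <- brute_force_distance(m) <= 5 / 0.5   # 10 px radius
  expect_identical(e$mask, oracle)
  expect_true(all(e$mask[m]))                    # superset of input
})

test_that("arbitrary masks expand exactly per the Euclidean metric", {
  set.seed(7)
  for (rep in 1:3) {
    m <- matrix(runif(48 * 48) < 0.02, 48, 48)
    if (!any(m)) next
    e <- expand_epithelium(binary_mask(m, 1, "epithelium"), 4)
    expect_identical(e$mask, brute_force_distance(m) <= 4)
  }
})

test_that("a zero-width band leaves only epithelium and lamina propria", {
  g <- generate_tissue_image(small_spec(seed = 1))
  maps <- build_compartments(g$truth$tissue_mask, g$truth$epithelium_mask,
                             expanded = expand_epithelium(g$truth$epithelium_mask, 0))
  expect_equal(unname(maps$areas_mm2[["subepithelial"]]), 0)
  lp <- maps$labels == COMPARTMENT_LEVELS[["lamina_propria"]]
  expect_identical(lp, g$truth$tissue_mask$mask & !g$truth$epithelium_mask$mask)
})

test_that("a disk epithelium produces the exact 20-25 um annulus", {
  h <- w <- 101
  ctr <- 51
  dist <- sqrt(outer((1:h - ctr)^2, (1:w - ctr)^2, "+"))
  epi <- dist <= 20                      # mpp 1: 20 um disk
  tissue <- matrix(TRUE, h, w)
  maps <- build_compartments(binary_mask(tissue, 1, "tissue"),
                             binary_mask(epi, 1, "epithelium"),
                             distance_um = 5)
  band <- maps$labels == COMPARTMENT_LEVELS[["subepithelial"]]
  oracle <- (brute_force_distance(epi) <= 5) & !epi
  expect_identical(band, oracle)
})

test_that("compartment labels partition the tissue exactly", {
  set.seed(11)
  for (rep in 1:20) {
    tissue <- matrix(runif(40 * 40) < 0.6, 40, 40)
    epi <- tissue & matrix(runif(40 * 40) < 0.3, 40, 40)
    maps <- build_compartments(binary_mask(tissue, 0.7, "tissue"),
                               binary_mask(epi, 0.7, "epithelium"),
                               distance_um = 3)
    lab <- maps$labels
    expect_identical(lab != 0, tissue)                       # exhaustive
    expect_identical(lab == 1, epi)                          # exclusive
    expect_equal(sum(maps$areas_mm2[COMPARTMENTS]),
                 unname(maps$areas_mm2[["tissue"]]))
  }
})

test_that("band construction is monotone in the expansion distance", {
  g <- generate_tissue_image(small_spec(seed = 2))
  e3 <- expand_epithelium(g$truth$epithelium_mask, 3)
  e5 <- expand_epithelium(g$truth$epithelium_mask, 5)
  e8 <- expand_epithelium(g$truth$epithelium_mask, 8)
  expect_true(all(e5$mask[e3$mask]))
  expect_true(all(e8$mask[e5$mask]))
})

test_that("violated preconditions are reported", {
  tissue <- binary_mask(matrix(FALSE, 10, 10), 1, "tissue")
  epi <- binary_mask(matrix(TRUE, 10, 10), 1, "epithelium")
  expect_error(build_compartments(tissue, epi), "subset")
})

test_that("compartment maps round-trip through PNG + JSON", {
  g <- generate_tissue_image(small_spec(seed = 2))
  p <- withr::local_tempfile(fileext = ".png")
  write_compartments(g$truth$compartments, p)
  back <- read_compartments(p)
  expect_identical(back$labels, g$truth$compartments$labels)
  expect_equal(back$areas_mm2, g$truth$compartments$areas_mm2,
               tolerance = 1e-12)
})
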