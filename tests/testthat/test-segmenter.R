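# three texture-distinct tiles: train on two, hold out the third
make_tiles <- function(seeds = 1:3) {
  lapply(seeds, function(s) generate_tissue_image(small_spec(seed = s)))
}

test_that("the segmenter reaches held-out IoU >= 0.80 on synthetic tiles", {
  gs <- make_tiles()
  seg <- train_epithelium_segmenter(
    lapply(gs[1:2], `[[`, "image"),
    lapply(gs[1:2], function(g) g$truth$epithelium_mask),
    seed = 5
  )
  pred <- predict_epithelium(gs[[3]]$image, seg)
  expect_gte(iou(pred$mask, gs[[3]]$truth$epithelium_mask$mask), 0.80)
})

test_that("retraining with the same seed reproduces identical masks", {
  gs <- make_tiles(seeds = c(4, 5))
  args <- list(list(gs[[1]]$image), list(gs[[1]]$truth$epithelium_mask),
               seed = 9)
  seg1 <- do.call(train_epithelium_segmenter, args)
  seg2 <- do.call(train_epithelium_segmenter, args)
  p1 <- predict_epithelium(gs[[2]]$image, seg1)
  p2 <- predict_epithelium(gs[[2]]$image, seg2)
  expect_identical(p1$mask, p2$mask)
})

test_that("predictions never leave the tissue mask and specks are removed", {
  gs <- make_tiles(seeds = c(4, 5))
  seg <- train_epithelium_segmenter(list(gs[[1]]$image),
                                    list(gs[[1]]$truth$epithelium_mask),
                                    seed = 9)
  st <- separate_stains(gs[[2]]$image)
  tissue <- segment_tissue(st)
  pred <- predict_epithelium(gs[[2]]$image, seg, tissue = tissue)
  expect_false(any(pred$mask & !tissue$mask))
  # minimum-area rule: no connected component below the threshold
  lab <- EBImage::bwlabel(pred$mask * 1L)
  if (max(lab) > 0) {
    min_px <- 0.0005 / (0.5 / 1000)^2
    expect_true(all(tabulate(as.integer(lab)) >= min_px))
  }
})

test_that("single-class annotations raise a degenerate-training error", {
  g <- generate_tissue_image(small_spec(seed = 6))
  all_epi <- binary_mask(matrix(TRUE, 256, 256), 0.5, "epithelium")
  expect_error(
    train_epithelium_segmenter(list(g$image), list(all_epi), seed = 1),
    "single class"
  )
})

test_that("misaligned annotations and untrained models are rejected", {
  g <- generate_tissue_image(small_spec(seed = 6))
  wrong <- binary_mask(matrix(FALSE, 10, 10), 0.5, "epithelium")
  expect_error(train_epithelium_segmenter(list(g$image), list(wrong)),
               "align")
  expect_error(predict_epithelium(g$image, structure(list(),
                                                    class = "list")),
               "not a trained")
})

test_that("a serialised segmenter reloads and predicts identically", {
  gs <- make_tiles(seeds = c(7, 8))
  seg <- train_epithelium_segmenter(list(gs[[1]]$image),
                                    list(gs[[1]]$truth$epithelium_mask),
                                    seed = 2)
  p <- withr::local_tempfile(fileext = ".rds")
  save_segmenter(seg, p)
  back <- load_segmenter(p)
  expect_equal(back$format_version, 1L)
  expect_identical(predict_epithelium(gs[[2]]$image, back)$mask,
                   predict_epithelium(gs[[2]]$image, seg)$mask)
})

test_that("annotation polygons can stand in for the segmenter", {
  # rasterised rectangle annotation used directly as the epithelium mask
  g <- generate_tissue_image(small_spec(
    seed = 2, cell_density = c(epithelium = 0, subepithelial = 0,
                               lamina_propria = 500)))
  rect <- list(type = "Feature", properties = NULL,
               geometry = list(type = "Polygon",
                               coordinates = list(list(c(60, 60), c(200, 60),
                                                       c(200, 120), c(60, 120),
                                                       c(60, 60)))))
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list(rect)),
                       f, auto_unbox = TRUE, digits = NA)
  ann <- load_annotation_polygons(f, 256, 256, 0.5)
  expect_equal(sum(ann$mask), 140 * 60)
  expect_s3_class(ann, "binary_mask")
})
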