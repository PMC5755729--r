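test_that("grid dimensions follow the region bounding box", {
  expect_equal(nrow(build_grid(rect_region(0, 0, 1500, 1500), mpp = 1)), 9)
  expect_equal(nrow(build_grid(rect_region(0, 0, 1501, 1500), mpp = 1)), 12)
  expect_equal(nrow(build_grid(rect_region(100, 100, 400, 300), mpp = 1)), 1)
  # tile side converts through mpp: 500 um at 0.5 um/px = 1000 px
  g <- build_grid(rect_region(0, 0, 3000, 3000), mpp = 0.5)
  expect_equal(attr(g, "tile_side_px"), 1000)
  expect_equal(nrow(g), 9)
})

test_that("tiles that miss a non-rectangular region are dropped", {
  # thin L-shape: bounding box 1500x1500 but only 5 tiles touch it
  l_shape <- region_annotation(cbind(
    c(0, 1500, 1500, 400, 400, 0),
    c(0, 0, 400, 400, 1500, 1500)))
  g <- build_grid(l_shape, mpp = 1)
  expect_equal(nrow(g), 5)
})

test_that("degenerate regions and bad parameters are rejected", {
  expect_error(region_annotation(cbind(c(0, 1, 2), c(0, 0, 0))), "area")
  expect_error(build_grid(rect_region(0, 0, 10, 10), mpp = -1), "positive")
  expect_error(hot_spot_index(make_tiles(10, 1), k = 0), "positive")
})

test_that("counting honors the region polygon, not its bounding box", {
  tri <- region_annotation(cbind(c(0, 1000, 0), c(0, 0, 1000)))
  tiles <- build_grid(tri, mpp = 1)
  det <- tibble::tibble(
    x_px = c(100, 100, 900, 499.9),  # last two: outside / inside hypotenuse
    y_px = c(100, 200, 900, 499.9),
    area_px2 = 20, mean_dab_od = c(0.5, 0, 0.5, 0.5), mean_hema_od = 0.5,
    label = c("positive", "negative", "positive", "positive"))
  counted <- count_per_tile(det, tiles, tri)
  expect_equal(sum(counted$total_cells), 3)  # (900,900) excluded
  expect_equal(sum(counted$positive_cells), 2)
})

test_that("a single-tile region gives the plain percentage", {
  reg <- rect_region(0, 0, 499, 499)
  tiles <- build_grid(reg, mpp = 1)
  set.seed(1)
  det <- tibble::tibble(x_px = runif(1000, 0, 499), y_px = runif(1000, 0, 499),
                        area_px2 = 20, mean_dab_od = 0, mean_hema_od = 0.5,
                        label = rep(c("positive", "negative"), c(300, 700)))
  counted <- count_per_tile(det, tiles, reg)
  expect_equal(nrow(counted), 1)
  expect_equal(counted$total_cells, 1000)
  expect_equal(counted$percent_positive, 30)
})

test_that("hot-spot index averages the top five qualifying tiles", {
  t7 <- make_tiles(total = rep(600, 7), positive = 60 * (1:7))
  expect_equal(hot_spot_index(t7)$hot_spot_index, 50)
  t3 <- make_tiles(total = rep(600, 3), positive = 60 * (1:3))
  hs3 <- hot_spot_index(t3)
  expect_equal(hs3$hot_spot_index, 20)
  expect_equal(hs3$n_hotspot_tiles_used, 3L)
  flat <- make_tiles(total = rep(600, 9), positive = rep(60, 9))
  expect_equal(hot_spot_index(flat)$hot_spot_index, 10)
})

test_that("tiles below the cell minimum cannot become hot spots", {
  tiles <- make_tiles(total = c(600, 600, 499, 100),
                      positive = c(60, 120, 499, 100))
  hs <- hot_spot_index(tiles)
  expect_equal(hs$n_qualifying_tiles, 2L)
  expect_equal(hs$hot_spot_index, mean(c(10, 20)))
  none <- make_tiles(total = c(10, 20), positive = c(1, 2))
  expect_warning(res <- hot_spot_index(none), "undefined")
  expect_true(is.na(res$hot_spot_index))
  expect_true(res$hotspot_undefined)
})

test_that("whole-slide index is the macro mean over counted tiles", {
  # 0% of 100 cells and 100% of 1000 cells: macro mean 50, not pooled 90.9
  two <- make_tiles(total = c(100, 1000), positive = c(0, 1000))
  expect_equal(whole_slide_index(two)$whole_slide_index, 50)
  seven <- make_tiles(total = rep(600, 7), positive = 60 * (1:7))
  expect_equal(whole_slide_index(seven)$whole_slide_index, 40)
  # zero-cell tiles are excluded, not treated as 0%
  with_empty <- make_tiles(total = c(600, 0), positive = c(300, 0))
  expect_equal(whole_slide_index(with_empty)$whole_slide_index, 50)
  expect_equal(with_empty$percent_positive[2], NA_real_)
  all_empty <- make_tiles(total = c(0, 0), positive = c(0, 0))
  expect_true(is.na(whole_slide_index(all_empty)$whole_slide_index))
})

test_that("hot-spot index dominates the qualifying-tile mean", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:25, 1)
    total <- rpois(n, 600)
    positive <- rbinom(n, total, runif(1))
    tiles <- make_tiles(total, positive)
    qual <- tiles[tiles$total_cells >= 500, ]
    if (nrow(qual) == 0) next
    hs <- hot_spot_index(tiles)$hot_spot_index
    expect_gte(hs, mean(qual$percent_positive) - 1e-12)
  }
})

test_that("counts partition the in-region detections exactly", {
  sim <- simulate_slide(small_slide_spec(seed = 6))
  tiles <- build_grid(sim$region, 1)
  counted <- count_per_tile(sim$truth, tiles, sim$region)
  inside <- points_in_region(sim$truth$x_px, sim$truth$y_px, sim$region)
  expect_equal(sum(counted$total_cells), sum(inside))
  expect_equal(sum(counted$positive_cells),
               sum(inside & sim$truth$label == "positive"))
})

test_that("indices are scale-invariant in the counts and bounded", {
  tiles <- make_tiles(total = c(600, 800, 1000), positive = c(60, 400, 900))
  doubled <- make_tiles(total = 2 * c(600, 800, 1000),
                        positive = 2 * c(60, 400, 900))
  expect_equal(hot_spot_index(tiles)$hot_spot_index,
               hot_spot_index(doubled)$hot_spot_index)
  expect_equal(whole_slide_index(tiles)$whole_slide_index,
               whole_slide_index(doubled)$whole_slide_index)
  expect_true(dplyr::between(hot_spot_index(tiles)$hot_spot_index, 0, 100))
  expect_true(dplyr::between(whole_slide_index(tiles)$whole_slide_index,
                             0, 100))
})

test_that("tie-breaking makes repeated scoring byte-identical", {
  sim <- simulate_slide(small_slide_spec(seed = 2))
  s1 <- score_slide(sim$image, sim$region)
  s2 <- score_slide(sim$image, sim$region)
  expect_identical(s1$tiles, s2$tiles)
  expect_identical(s1$summary, s2$summary)
})

test_that("a slide with one hot spot scores hot-spot above whole-slide", {
  sim <- simulate_slide(small_slide_spec(seed = 3))
  sc <- score_slide(sim$image, sim$region)
  expect_gt(sc$summary$hot_spot_index, sc$summary$whole_slide_index)
})

test_that("an empty annotation is rejected", {
  sim <- simulate_slide(small_slide_spec(seed = 2))
  expect_error(score_slide(sim$image, list()), "region_annotation")
})
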