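test_that("green-band thresholding is exact at the boundary", {
  below <- uniform_rgb(8, 8, c(255, 219, 255))
  expect_true(all(threshold_green(below, 220) == 0))
  at <- uniform_rgb(8, 8, c(0, 220, 0))
  expect_true(all(threshold_green(at, 220) == 255))
  white <- uniform_rgb(8, 8, c(255, 255, 255))
  expect_true(all(threshold_green(white, 220) == 255))
  expect_error(threshold_green(matrix(0, 8, 8)), "RGB")
})

test_that("particle measurement matches shape oracles", {
  expect_equal(nrow(find_particles(matrix(0, 20, 20))), 0)

  # digital circle, radius 20: area within 2% of pi r^2, circularity >= 0.9
  d <- disk_matrix(20)
  p <- find_particles(d)
  expect_equal(nrow(p), 1)
  expect_lt(abs(p$area - pi * 400) / (pi * 400), 0.02)
  expect_gte(p$circularity, 0.9)
  expect_lte(p$circularity, 1)

  # two disjoint squares under the naive pixel-edge perimeter: pi/4 each
  sq <- matrix(0, 40, 60)
  sq[5:14, 5:14] <- 255
  sq[20:34, 30:44] <- 255
  ps <- find_particles(sq, perimeter = "edges")
  expect_equal(nrow(ps), 2)
  expect_equal(ps$area, c(100, 225))
  expect_equal(ps$circularity, rep(pi / 4, 2), tolerance = 1e-12)

  # labelling is deterministic, row-major by first pixel:
  # the square starting at row 5 comes first
  expect_lt(ps$centroid_row[1], ps$centroid_row[2])
})

test_that("chain perimeter keeps digitised circles above the 0.5 filter", {
  for (dia in c(12, 20, 40, 80, 120)) {
    p <- find_particles(disk_matrix(dia / 2))
    expect_gte(p$circularity, 0.88)
    expect_lte(p$circularity, 1)
  }
})

test_that("connectivity setting controls diagonal merging", {
  m <- matrix(0, 10, 10)
  m[3, 3] <- 255; m[4, 4] <- 255
  expect_equal(nrow(find_particles(m, connectivity = 8)), 1)
  expect_equal(nrow(find_particles(m, connectivity = 4)), 2)
})

test_that("particles with holes are measured solid", {
  ring <- matrix(0, 30, 30)
  ring[(row(ring) - 15)^2 + (col(ring) - 15)^2 <= 100] <- 255
  ring[(row(ring) - 15)^2 + (col(ring) - 15)^2 <= 9] <- 0
  p <- find_particles(ring)
  solid <- find_particles(disk_matrix(10))
  expect_equal(p$area, solid$area)
})

test_that("size and circularity bounds are inclusive", {
  cfg <- morphometry_config()
  parts <- data.frame(label = 1:5,
                      area = c(99, 100, 5000, 10000, 10001),
                      perimeter = 1,
                      circularity = c(0.9, 0.5, 0.4, 1.0, 0.9),
                      centroid_row = 1, centroid_col = 1,
                      touches_border = FALSE)
  kept <- filter_particles(parts, cfg)
  # 99 px too small; circ 0.4 vessel-like; 10001 px too large
  expect_equal(kept$label, c(2, 4))
})

test_that("tissue area fills interior holes and rejects empty sections", {
  # solid tissue rectangle with interior holes: binary has bright holes
  bin <- matrix(255, 60, 60)           # slide background all bright
  bin[10:49, 10:49] <- 0               # tissue block
  bin[20:24, 20:24] <- 255             # interior hole (vacuole)
  bin[30:38, 35:40] <- 255             # another hole
  expect_equal(tissue_area(bin), 40 * 40)
  expect_error(tissue_area(matrix(255, 10, 10)), "undefined")
})

test_that("full morphometry recovers phantom ground truth", {
  spec <- histology_phantom_spec(width = 512, height = 512,
                                 target_fat_fraction = 0.10,
                                 n_vessels = 0, n_tears = 0, seed = 9)
  ph <- generate_histology_phantom(spec)
  res <- areal_fat_fraction(ph$image)
  expect_lt(abs(res$areal_fat_fraction / ph$true_areal_fat_fraction - 1), 0.10)
  # with non-touching in-bounds vacuoles, the fat area matches the mask
  # within boundary discretisation
  expect_lt(abs(res$fat_area - sum(ph$fat_mask)),
            sum(res$particles$accepted * res$particles$perimeter))
  # tissue area within 1% of ground truth
  expect_lt(abs(res$tissue_area / sum(ph$tissue_mask) - 1), 0.01)
  # the thresholded binary equals the union of bright ground-truth regions
  bin <- threshold_green(ph$image)
  truth <- ph$fat_mask | ph$vessel_mask | !ph$tissue_mask
  expect_true(all((bin == 255) == truth))
})

test_that("zero-fat phantom yields exactly zero fat fraction", {
  spec <- histology_phantom_spec(width = 256, height = 256,
                                 target_fat_fraction = 0,
                                 n_vessels = 0, n_tears = 0, seed = 2)
  ph <- generate_histology_phantom(spec)
  res <- areal_fat_fraction(ph$image)
  expect_identical(res$areal_fat_fraction, 0)
})

test_that("vessels and tears are excluded without corrupting the denominator", {
  spec <- histology_phantom_spec(width = 640, height = 640,
                                 target_fat_fraction = 0.05,
                                 n_vessels = 1, n_tears = 1, seed = 21)
  ph <- generate_histology_phantom(spec)
  res <- areal_fat_fraction(ph$image)
  expect_lt(abs(res$areal_fat_fraction / ph$true_areal_fat_fraction - 1), 0.10)
  rejected <- res$particles[!res$particles$accepted & !res$particles$touches_border, ]
  # the vessel is oversize, the tear is low-circularity
  expect_true(any(rejected$area > 10000))
  expect_true(any(rejected$circularity < 0.5))
})

test_that("adding an in-bounds vacuole strictly increases the fat fraction", {
  spec <- histology_phantom_spec(width = 400, height = 400,
                                 target_fat_fraction = 0.04,
                                 n_vessels = 0, n_tears = 0, seed = 5)
  ph <- generate_histology_phantom(spec)
  base <- areal_fat_fraction(ph$image)
  img2 <- ph$image
  # paint one extra 30 px diameter vacuole in a fat-free tissue spot
  ctr <- c(200, 200)
  stopifnot(ph$tissue_mask[ctr[1], ctr[2]], !ph$fat_mask[ctr[1], ctr[2]])
  disk <- (row(ph$fat_mask) - ctr[1])^2 + (col(ph$fat_mask) - ctr[2])^2 <= 15^2
  for (ch in 1:3) {
    plane <- img2[, , ch]; plane[disk] <- 250; img2[, , ch] <- plane
  }
  more <- areal_fat_fraction(img2)
  expect_gt(more$areal_fat_fraction, base$areal_fat_fraction)
  # and rerunning on the same image is bit-identical (idempotence)
  again <- areal_fat_fraction(ph$image)
  expect_identical(base$areal_fat_fraction, again$areal_fat_fraction)
  expect_identical(base$particles, again$particles)
})

test_that("equivalent-circle diameter mapping is self-consistent", {
  ps <- pixel_size_from_anchor(100, 5.6)
  expect_equal(equivalent_diameter_um(100, ps), 5.6, tolerance = 1e-12)
  # area scales as diameter squared: 100x the area, 10x the diameter
  expect_equal(equivalent_diameter_um(10000, ps), 56, tolerance = 1e-12)
})
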