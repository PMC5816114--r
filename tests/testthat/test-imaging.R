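# Segmentation and feature measurement against closed-form geometry.

test_that("segmentation handles blank, simple and synthetic images", {
  cfg <- segmentation_config()
  expect_equal(max(segment_particles(matrix(0.1, 50, 50), cfg)), 0)
  expect_error(segment_particles(array(0, c(4, 4, 2)), cfg), "2D")

  img <- matrix(0.05, 120, 120)
  img[outer(1:120, 1:120, function(y, x) (x - 30)^2 + (y - 30)^2 <= 100)] <- 0.9
  img[outer(1:120, 1:120, function(y, x) (x - 85)^2 + (y - 85)^2 <= 144)] <- 0.9
  mask <- segment_particles(img, cfg)
  expect_equal(max(mask), 2)

  pl <- data.frame(x = c(50, 150, 250, 50, 170), y = c(50, 50, 60, 180, 190),
                   target_feret = c(40, 45, 50, 42, 38),
                   target_circularity = 0.9,
                   class = "pellet", stringsAsFactors = FALSE)
  r <- render_image(image_spec(canvas_size = c(320, 320), pellets = pl, seed = 4))
  mask <- segment_particles(r$image, cfg)
  expect_equal(max(mask), 5)
  m <- measure_particles(mask, r$image)
  for (i in 1:5) {
    d <- sqrt((m$centroid_x - (pl$x[i] - 1))^2 + (m$centroid_y - (pl$y[i] - 1))^2)
    expect_lt(min(d), 3)  # each ground-truth position has a matching object
  }
})

test_that("small and border-touching particles are filtered as configured", {
  img <- matrix(0, 80, 80)
  img[10:40, 10:40] <- 1            # large interior object
  img[60:62, 60:62] <- 1            # speck
  img[1:15, 70:80] <- 1             # touches the border
  keep_all <- segment_particles(img, segmentation_config(
    threshold_method = "fixed", fixed_threshold = 0.5,
    exclude_edge_touching = FALSE))
  expect_equal(max(keep_all), 3)
  no_edge <- segment_particles(img, segmentation_config(
    threshold_method = "fixed", fixed_threshold = 0.5))
  expect_equal(max(no_edge), 2)
  big_only <- segment_particles(img, segmentation_config(
    threshold_method = "fixed", fixed_threshold = 0.5, min_area = 100))
  expect_equal(max(big_only), 1)
})

test_that("a rasterized disk reproduces closed-form circle geometry", {
  m <- measure_mask(mask_disk(50))
  expect_lt(abs(m$area - pi * 50^2) / (pi * 50^2), 0.02)
  expect_lt(abs(m$max_feret - 100) / 100, 0.02)
  expect_lt(abs(m$min_feret - 100) / 100, 0.02)
  expect_lt(abs(m$perimeter - 2 * pi * 50) / (2 * pi * 50), 0.02)
  expect_gte(m$circularity, 0.95)
  expect_lte(m$circularity, 1)
  expect_gte(m$roundness, 0.95)
  expect_lt(abs(m$ellipse_perimeter - 2 * pi * 50) / (2 * pi * 50), 0.02)
  expect_lt(abs(m$bmd - 2), 0.1)
  expect_lt(abs(m$bsd - 1), 0.1)
  expect_gt(m$perimeter_ratio, 0.95)
})

test_that("a rasterized rectangle reproduces closed-form geometry", {
  m <- measure_mask(mask_rect(100, 50))
  expect_equal(m$area, 5000)
  expect_lt(abs(m$max_feret - sqrt(100^2 + 50^2)) / sqrt(100^2 + 50^2), 0.02)
  expect_lt(abs(m$min_feret - 50) / 50, 0.02)
  expect_lt(abs(m$circularity - 4 * pi * 5000 / 300^2), 0.05)
})

test_that("box-counting dimensions match constructions of known dimension", {
  expect_lt(abs(measure_mask(mask_line(200))$bsd - 1), 0.1)
  koch <- mask_koch(4, 1)
  bidx <- which(koch, arr.ind = TRUE)
  d <- pelletmorph:::box_surface_dimension(bidx, max(dim(koch)))
  expect_lt(abs(d - 1.5), 0.15)
})

test_that("features are equivariant under pixel-size rescaling", {
  m1 <- measure_mask(mask_rect(80, 40), pixel_size = 1)
  m2 <- measure_mask(mask_rect(80, 40), pixel_size = 2)
  expect_equal(m2$area, 4 * m1$area)
  expect_equal(m2$max_feret, 2 * m1$max_feret)
  expect_equal(m2$min_feret, 2 * m1$min_feret)
  expect_equal(m2$perimeter, 2 * m1$perimeter)
  expect_equal(m2$ellipse_perimeter, 2 * m1$ellipse_perimeter)
  expect_equal(m2$circularity, m1$circularity)
  expect_equal(m2$roundness, m1$roundness)
  expect_equal(m2$bmd, m1$bmd)
  expect_equal(m2$bsd, m1$bsd)
})

test_that("features are invariant under object rotation", {
  m0 <- measure_mask(mask_rect(100, 50))
  for (angle in c(pi / 6, pi / 4, 1.1)) {
    mr <- measure_mask(mask_rot_rect(100, 50, angle))
    expect_lt(abs(mr$max_feret - m0$max_feret) / m0$max_feret, 0.03)
    expect_lt(abs(mr$area - m0$area) / m0$area, 0.03)
    expect_lt(abs(mr$circularity - m0$circularity), 0.05)
  }
})

test_that("circularity orders disk above ellipse above star", {
  disk <- measure_mask(mask_disk(40))
  ell <- measure_mask(mask_ellipse(57, 28))   # similar area, elongated
  star <- measure_mask(mask_star(45))         # similar area, ruffled boundary
  expect_gt(disk$circularity, ell$circularity)
  expect_gt(ell$circularity, star$circularity)
})

test_that("hull-based max Feret equals brute force over boundary corners", {
  set.seed(77)
  for (rep in 1:10) {
    M <- matrix(runif(400) < 0.3, 20, 20)
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(M)))
    if (max(lab) == 0) next
    counts <- tabulate(lab[lab > 0])
    M1 <- lab == which.max(counts)
    m <- measure_mask(M1)
    cc <- pelletmorph:::corner_cloud(M1 == 1)
    brute <- max(dist(cc))
    expect_identical(m$max_feret, brute)
  }
})

test_that("degenerate single-pixel particles are flagged", {
  M <- matrix(FALSE, 9, 9); M[5, 5] <- TRUE
  m <- measure_mask(M)
  expect_true(m$degenerate)
  expect_true(is.na(m$bmd))
  expect_true(is.na(m$bsd))
  expect_equal(m$area, 1)
})

test_that("exclusions filter records without touching the input", {
  recs <- two_cluster_records(n_per = 30)
  recs$image_id <- "img1"
  expect_message(same <- exclude_particles(recs, recs[0, c("image_id", "label")]),
                 "excluding 0")
  expect_equal(same, recs)
  expect_message(none <- exclude_particles(recs, recs[, c("image_id", "label")]),
                 "excluding 60")
  expect_equal(nrow(none), 0)
  thr <- median(recs$sd_intensity)
  expect_message(kept <- exclude_particles(recs, function(r) r$sd_intensity < thr))
  expect_equal(nrow(kept), sum(recs$sd_intensity >= thr))
  expect_warning(exclude_particles(recs, data.frame(image_id = "nope", label = 1)),
                 "unknown")
})
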