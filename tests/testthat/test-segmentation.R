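test_that("psd95_synapse_labels finds nothing in noise and splits touching puncta", {
  set.seed(21)
  # noise-only field: no structure above the threshold survives the size filter
  noise <- matrix(rpois(200 * 200, 20) + rnorm(200 * 200, 0, 2), 200)
  noise <- pmax(noise, 0)
  lab <- psd95_synapse_labels(noise, maxima_prominence = 5, pixel_size_nm = 100)
  # a handful of chance specks can survive; the field must be essentially empty
  expect_lt(n_labels(lab), 5)

  # two blobs whose Otsu masks merge but whose maxima split them
  f <- planted_spot_field(c(60, 60), 0.1, rbind(c(2.5, 3), c(3.3, 3)),
                          area_um2 = 0.12, amplitude = 300,
                          psf_sigma_um = 0.13, background = 20)
  lab2 <- psd95_synapse_labels(f, maxima_prominence = 5, pixel_size_nm = 100)
  expect_equal(n_labels(lab2), 2)

  # without maxima splitting the same blobs form one Otsu component
  b <- gaussian_blur(f, 2)
  comp <- synaptiq:::cpp_label_components(b > threshold_otsu(b))
  expect_equal(max(comp), 1)
})

test_that("a single planted punctum is recovered with accurate centroid and area", {
  # STED-scale zero-noise rendering: detected area within 15% of the
  # above-half-max footprint, centroid within one pixel
  px_um <- 0.02
  a <- sqrt(0.11 * 1.3 / pi); b <- sqrt(0.11 / (1.3 * pi))
  dims <- c(150, 150)
  canvas <- matrix(0, dims[1], dims[2])
  canvas[synaptiq:::ellipse_indices(dims, px_um, 1.5, 1.5, a, b, 0.7)] <- 40
  img <- gaussian_blur(canvas, 0.017 / px_um) + 8
  lab <- psd95_synapse_labels(img, maxima_prominence = 10, pixel_size_nm = 20)
  expect_equal(n_labels(lab), 1)
  props <- region_properties(lab)
  expect_lt(abs(props$centroid_x_um - 1.5), px_um)
  expect_lt(abs(props$centroid_y_um - 1.5), px_um)
  truth_area <- synaptiq:::half_max_area_um2(a, b, 0.017, px_um)
  expect_lt(abs(props$area_um2 - truth_area) / truth_area, 0.15)
})

test_that("synapse labels are offset-invariant, reproducible, and one-segment-per-label", {
  set.seed(22)
  centers <- cbind(runif(12, 1, 7), runif(12, 1, 7))
  f <- planted_spot_field(c(80, 80), 0.1, centers, 0.12, 300, 0.13)
  f <- f + matrix(rnorm(6400, 0, 1.5), 80)
  f <- pmax(f, 0)
  lab1 <- psd95_synapse_labels(f, 5, pixel_size_nm = 100)
  lab2 <- psd95_synapse_labels(f, 5, pixel_size_nm = 100)
  expect_identical(lab1$labels, lab2$labels)          # bit-reproducible
  lab3 <- psd95_synapse_labels(f + 37, 5, pixel_size_nm = 100)
  expect_identical(lab1$labels, lab3$labels)          # offset-invariant

  # every label lies inside exactly one maxima segment
  b <- gaussian_blur(f, 2)
  segs <- find_maxima(b, 5, mode = "segmented")$segments
  for (k in seq_len(n_labels(lab1))) {
    expect_equal(length(unique(segs[lab1$labels == k])), 1)
  }

  # constant image degenerates to an empty map with a warning
  expect_warning(lab0 <- psd95_synapse_labels(matrix(7, 30, 30), 5,
                                              pixel_size_nm = 100),
                 "constant")
  expect_equal(n_labels(lab0), 0)
})

test_that("soma segmentation applies the size filter and exclusion annotations", {
  set.seed(24)
  px_um <- 0.5
  dims <- c(120, 160)
  canvas <- matrix(0, dims[1], dims[2])
  # two discs of diameter 15 um at 3x background, one small disc below the cut
  for (ctr in list(c(15, 15), c(60, 30))) {
    idx <- synaptiq:::ellipse_indices(dims, px_um, ctr[1], ctr[2], 7.5, 7.5, 0)
    canvas[idx] <- 400
  }
  canvas[synaptiq:::ellipse_indices(dims, px_um, 40, 45, 1.2, 1.2, 0)] <- 400
  pv <- gaussian_blur(canvas, 0.4 / px_um) + 200
  pv <- matrix(rpois(length(pv), as.vector(pv)), nrow(pv))
  som <- soma_labels(pv, min_area_um2 = 50, pixel_size_nm = 500)
  expect_equal(n_labels(som), 2)

  # raising the minimum above the disc area removes everything
  som_big <- soma_labels(pv, min_area_um2 = 400, pixel_size_nm = 500)
  expect_equal(n_labels(som_big), 0)

  # excluding one region by id leaves one soma
  som_ex <- soma_labels(pv, min_area_um2 = 50, exclusions = 1L,
                        pixel_size_nm = 500)
  expect_equal(n_labels(som_ex), 1)
})

test_that("neuropil background mask is disjoint from the PV-positive mask and estimates background", {
  set.seed(23)
  px_um <- 0.5
  dims <- c(100, 100)
  canvas <- matrix(0, dims[1], dims[2])
  canvas[synaptiq:::ellipse_indices(dims, px_um, 20, 20, 7.5, 7.5, 0)] <- 800
  pv <- gaussian_blur(canvas, 0.4 / px_um) + 20
  pv <- matrix(rpois(length(pv), pv), nrow(pv))
  m <- neuropil_background_mask(pv)
  pos <- pv > threshold_mean(pv)
  expect_false(any(m & pos))
  expect_lt(abs(mean(pv[m]) - 20), 2)

  # unimodal all-background field: mask covers roughly half the pixels
  # (integer-valued noise puts the sample mean inside one count bin, so the
  # covered fraction can fall a few points either side of one half)
  bgonly <- matrix(rpois(10000, 20), 100)
  expect_gt(mean(neuropil_background_mask(bgonly)), 0.40)
  expect_lt(mean(neuropil_background_mask(bgonly)), 0.75)
  # conditioning on being at or below the mean truncates the upper tail, so
  # the masked mean sits a little below the true background
  expect_lt(abs(mean(bgonly[neuropil_background_mask(bgonly)]) - 20), 5)
})

test_that("summed-channel segmentation rescues weak-PSD95 synapses and commutes", {
  px_um <- 0.1
  # one synapse whose PSD-95 alone is sub-threshold but whose summed signal is not
  weak <- planted_spot_field(c(60, 60), px_um, cbind(3, 3), 0.12, 18, 0.13,
                             background = 10)
  strong_sum <- planted_spot_field(c(60, 60), px_um, cbind(3, 3), 0.12, 60,
                                   0.13, background = 10)
  empty <- matrix(10, 60, 60)
  # PSD-95 alone: Otsu threshold on a near-flat image finds no punctum
  lab_alone <- psd95_synapse_labels(weak, 5, pixel_size_nm = 100)
  lab_sum <- summed_channel_labels(weak, strong_sum, weak, 5,
                                   pixel_size_nm = 100)
  expect_equal(n_labels(lab_sum), 1)

  # permuting channels yields identical labels
  lab_perm <- summed_channel_labels(strong_sum, weak, weak, 5,
                                    pixel_size_nm = 100)
  expect_identical(lab_sum$labels, lab_perm$labels)

  # all-zero channels: degenerate, empty
  z <- matrix(0, 30, 30)
  expect_warning(lz <- summed_channel_labels(z, z, z, 5, pixel_size_nm = 100))
  expect_equal(n_labels(lz), 0)

  expect_error(summed_channel_labels(weak, matrix(0, 10, 10), weak, 5,
                                     pixel_size_nm = 100), "shape")
})

test_that("the PSD-95 integral filter keeps labels strictly above threshold", {
  px_um <- 0.1
  dims <- c(80, 80)
  canvas <- matrix(0, dims[1], dims[2])
  centers <- rbind(c(2, 2), c(5, 2), c(2, 5), c(5, 5))
  amps <- c(8, 30, 80, 200)
  for (k in 1:4) {
    idx <- synaptiq:::ellipse_indices(dims, px_um, centers[k, 1], centers[k, 2],
                                      0.2, 0.15, 0)
    canvas[idx] <- amps[k]
  }
  img <- gaussian_blur(canvas, 1.3)
  lab <- label_map(synaptiq:::cpp_label_components(img > 1), 100, "synapse")
  n0 <- n_labels(lab)
  expect_equal(n0, 4)
  bg <- matrix(0, dims[1], dims[2])
  ints <- per_synapse_intensity(lab, img, bg)

  # pick a threshold between the integrals of label 1 and the rest
  thr <- sort(ints$integral)[1] * 1.5
  kept <- filter_by_psd95_integral(lab, img, min_integral = thr, background = bg)
  expect_equal(n_labels(kept), sum(ints$integral > thr))

  # boundary semantics: a label exactly at the threshold is removed
  exact <- filter_by_psd95_integral(lab, img,
                                    min_integral = min(ints$integral),
                                    background = bg)
  expect_equal(n_labels(exact), 3)

  # min_integral = 0 keeps every label of a positive image
  all_kept <- filter_by_psd95_integral(lab, img, min_integral = 0,
                                       background = bg)
  expect_equal(n_labels(all_kept), n0)
})

test_that("dendrite annotations measure polyline length and rasterise masks over the polyline", {
  pl <- cbind(x_um = c(1, 4, 4), y_um = c(1, 1, 5))
  d <- dendrite_annotation("d1", pl, mask = matrix(FALSE, 60, 60))
  expect_equal(dendrite_length_um(d), 7)

  mask <- synaptiq:::polyline_mask(pl, c(60, 60), 100, halfwidth_um = 0.5)
  # every polyline vertex pixel is covered
  for (k in seq_len(nrow(pl))) {
    rr <- round(pl[k, 2] / 0.1 + 0.5); cc <- round(pl[k, 1] / 0.1 + 0.5)
    expect_true(mask[rr, cc])
  }
  # mask width is about 2 * halfwidth: area ~ length * width
  expect_lt(abs(sum(mask) * 0.01 - 7 * 1) / 7, 0.25)
})
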