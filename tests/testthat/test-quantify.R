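test_that("per-synapse intensities are background-subtracted means and sums", {
  lab <- matrix(0L, 10, 10); lab[3:5, 3:6] <- 1L
  lm <- label_map(lab, 100, "synapse")
  ch <- matrix(30, 10, 10); bg <- matrix(10, 10, 10)
  res <- per_synapse_intensity(lm, ch, bg)
  expect_equal(res$mean, 20)
  expect_equal(res$integral, 240)

  # channel identical to background: all zeros
  res0 <- per_synapse_intensity(lm, bg, bg)
  expect_equal(res0$integral, 0)

  # random field: per-label brute-force summation oracle
  set.seed(41)
  labr <- matrix(sample(0:5, 400, replace = TRUE), 20)
  lmr <- label_map(labr, 100, "synapse")
  chr <- matrix(runif(400, 0, 50), 20); bgr <- matrix(runif(400, 0, 20), 20)
  res_r <- per_synapse_intensity(lmr, chr, bgr)
  d <- pmax(chr - bgr, 0)
  for (k in seq_len(n_labels(lmr))) {
    expect_equal(res_r$integral[k], sum(d[lmr$labels == k]))
    expect_equal(res_r$mean[k], mean(d[lmr$labels == k]))
  }
  expect_error(per_synapse_intensity(lm, matrix(0, 5, 5), bg), "shape")
})

test_that("integrals are additive under label splitting", {
  set.seed(42)
  lab <- matrix(0L, 12, 12); lab[3:8, 3:8] <- 1L
  ch <- matrix(runif(144, 10, 60), 12); bg <- matrix(5, 12, 12)
  whole <- per_synapse_intensity(label_map(lab, 100, "synapse"), ch, bg)
  split <- lab; split[3:8, 6:8] <- 2L
  parts <- per_synapse_intensity(label_map(split, 100, "synapse"), ch, bg)
  expect_equal(sum(parts$integral), whole$integral)
})

test_that("PSD-95 normalisation returns unity at the population mean and respects gain structure", {
  rec <- data.frame(reaction = rep(c("r1", "r2"), each = 5),
                    psd95_mean = c(rep(10, 5), rep(40, 5)),
                    channel_mean = c(rep(10, 5), rep(40, 5)))
  out <- normalize_to_psd95(rec)
  expect_equal(out$normalized_mean, rep(1, 10))

  # doubling the paired channel doubles normalized values
  rec2 <- rec; rec2$channel_mean <- rec$channel_mean * 2
  expect_equal(normalize_to_psd95(rec2)$normalized_mean,
               2 * out$normalized_mean)

  # a shared gain applied to both channels of one reaction cancels
  rec3 <- rec
  g <- ifelse(rec3$reaction == "r2", 3.7, 1)
  rec3$psd95_mean <- rec3$psd95_mean * g
  rec3$channel_mean <- rec3$channel_mean * g
  expect_equal(normalize_to_psd95(rec3)$normalized_mean, out$normalized_mean)

  rec4 <- rec; rec4$psd95_mean <- 0
  expect_error(normalize_to_psd95(rec4), "zero")
})

test_that("a two-reaction cohort with a 2x gain difference normalises consistently", {
  # quantify the same physical field imaged at two detector gains
  set.seed(43)
  cfg <- generator_config(13, confocal = list(field_um = c(25, 50)))
  roster <- subject_roster(cfg)
  recs <- list()
  for (s in 1:3) {
    subject <- as.list(roster[s, ]); subject$index <- s
    fld <- simulate_field(cfg, subject, 1, "confocal_layer2")
    q1 <- quantify_layer2_field(fld$channels$PSD95, fld$channels$paired,
                                cfg$detect, reaction = "r1")
    gain2 <- function(p) { p$pixels <- p$pixels * 2; p }
    q2 <- quantify_layer2_field(gain2(fld$channels$PSD95),
                                gain2(fld$channels$paired),
                                cfg$detect, reaction = "r2")
    recs[[length(recs) + 1]] <- rbind(q1$records, q2$records)
  }
  rec <- do.call(rbind, recs)
  norm <- normalize_to_psd95(rec)
  m1 <- mean(norm$normalized_mean[norm$reaction == "r1"])
  m2 <- mean(norm$normalized_mean[norm$reaction == "r2"])
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("nanocluster counting resolves planted clusters and respects invariances", {
  px_um <- 0.02
  dims <- c(100, 100)
  lab <- matrix(0L, dims[1], dims[2])
  lab[synaptiq:::ellipse_indices(dims, px_um, 1, 1, 0.25, 0.2, 0)] <- 1L
  lm <- label_map(lab, 20, "synapse")
  munc <- matrix(5, dims[1], dims[2])
  # three clusters >= 60 nm apart at 5x background inside the synapse
  pts <- rbind(c(0.9, 0.95), c(1.05, 1.02), c(0.98, 1.12))
  for (k in 1:3)
    munc <- synaptiq:::add_gaussian_spot(munc, px_um, pts[k, 1], pts[k, 2],
                                         integral = 50 * 2 * pi * 0.021^2 / 0.02^2,
                                         sigma_um = 0.021)
  counts <- count_nanoclusters(munc, lm, dilate_px = 3, prominence = 10)
  expect_equal(counts$nanocluster_count, 3L)

  # empty channel: zero everywhere
  counts0 <- count_nanoclusters(matrix(5, dims[1], dims[2]), lm,
                                dilate_px = 3, prominence = 10)
  expect_equal(counts0$nanocluster_count, 0L)

  # invariant to adding a constant
  counts_c <- count_nanoclusters(munc + 50, lm, dilate_px = 3, prominence = 10)
  expect_equal(counts_c$nanocluster_count, counts$nanocluster_count)

  # non-increasing in prominence
  cc <- sapply(c(2, 5, 10, 20, 30), function(p)
    count_nanoclusters(munc, lm, dilate_px = 3, prominence = p)$nanocluster_count)
  expect_true(all(diff(cc) <= 0))
})

test_that("maxima points in overlapping dilated masks go to the nearest label", {
  lab <- matrix(0L, 30, 30)
  lab[10:12, 10:12] <- 1L
  lab[10:12, 18:20] <- 2L
  lm <- label_map(lab, 20, "synapse")
  munc <- matrix(0, 30, 30)
  munc[11, 14] <- 100  # 2 px from label 1, 4 px from label 2
  munc[11, 16] <- 90   # 4 px from label 1, 2 px from label 2
  counts <- count_nanoclusters(munc, lm, dilate_px = 4, prominence = 10)
  expect_equal(counts$nanocluster_count, c(1L, 1L))
})

test_that("nanocluster-area correlation behaves at the extremes and under the generator scaling", {
  rec <- data.frame(area_um2 = seq(0.02, 0.3, length.out = 20),
                    nanocluster_count = 1:20)
  expect_equal(nanocluster_area_correlation(rec)$r_s, 1)

  set.seed(44)
  n <- 500
  area <- rlnorm(n, log(0.11), 0.5)
  counts <- rpois(n, 3.4 / 0.11 * area)
  r <- nanocluster_area_correlation(data.frame(area_um2 = area,
                                               nanocluster_count = counts))
  expect_gt(r$r_s, 0.6)

  shuffled <- nanocluster_area_correlation(
    data.frame(area_um2 = area, nanocluster_count = sample(counts)))
  expect_lt(abs(shuffled$r_s), 0.15)

  expect_error(nanocluster_area_correlation(rec[1:2, ]), "n >= 3")
})

test_that("peak-aligned profiles align the reference to itself and honour box bounds", {
  fx <- make_sideview_fixture()
  pr <- peak_aligned_profile(fx$channels, fx$center, fx$direction,
                             reference = "PSD95")
  expect_equal(pr$offset_nm[pr$channel == "PSD95"], 0)
  expect_equal(pr$offset_nm[pr$channel == "GluA2"], 0)
  prof <- attr(pr, "profiles")
  expect_equal(unname(apply(prof, 2, max)), rep(1, 5))

  # reversing the box direction negates every offset
  pr_rev <- peak_aligned_profile(fx$channels, fx$center, -fx$direction,
                                 reference = "PSD95")
  expect_equal(pr_rev$offset_nm, -pr$offset_nm)

  # offsets are integer multiples of the pixel size
  expect_true(all(pr$offset_nm %% 20 == 0))

  # flat channel: warning, undefined peak
  flat <- fx$channels
  flat$Flat <- image_plane(matrix(3, 64, 96), 20, channel = "Flat")
  expect_warning(prf <- peak_aligned_profile(flat, fx$center, fx$direction,
                                             reference = "PSD95"), "flat")
  expect_true(is.na(prf$offset_nm[prf$channel == "Flat"]))

  # box exceeding image bounds
  expect_error(peak_aligned_profile(fx$channels, c(0.1, 0.1), fx$direction,
                                    reference = "PSD95"), "bounds")
})

test_that("PV-dendrite metrics compute ratios, overlap assignment and densities", {
  px_nm <- 100; px_um <- 0.1
  dims <- c(100, 100)
  lab <- matrix(0L, dims[1], dims[2])
  lab[20:23, 20:23] <- 1L   # on the dendrite
  lab[60:63, 60:63] <- 2L   # off the dendrite
  lab[80:83, 10:13] <- 3L   # off
  lm <- label_map(lab, px_nm, "synapse")
  pl <- cbind(x_um = c(1, 4), y_um = c(2.15, 2.15))
  mask <- synaptiq:::polyline_mask(pl, dims, px_nm, 0.5)
  dend <- list(dendrite_annotation("d1", pl, mask))
  # uniform channels make integrals proportional to amplitude x area
  mk <- function(a) { m <- matrix(0, dims[1], dims[2]); m[lab > 0] <- a; m }
  res <- pv_dendrite_metrics(lm, dend, channels = list(GluN1 = mk(50)),
                             psd95 = mk(100), background_radius_px = 2)
  syn <- res$synapses
  expect_equal(syn$on_pv_dendrite, c(TRUE, FALSE, FALSE))
  expect_equal(syn$dendrite_id[1], "d1")
  # ratio 50/100 for every synapse (flat rendering, no blur)
  expect_equal(syn$glun1_ratio, rep(0.5, 3), tolerance = 0.05)
  expect_equal(res$dendrites$length_um, 3)
  expect_equal(res$dendrites$synapse_count, 1L)
  expect_equal(res$dendrites$synapses_per_um, 1 / 3)

  # normalisation: PV ratio over the non-PV mean ratio
  syn$psd95_integral <- c(100, 100, 100)
  syn$glun1_integral <- c(50, 25, 25)
  syn$glun1_ratio <- syn$glun1_integral / syn$psd95_integral
  norm <- normalize_pv_ratios(syn)
  expect_equal(norm$normalized_glun1_density[1], 2)
  expect_true(all(is.na(norm$normalized_glun1_density[2:3])))

  # both scoping conventions agree here (equal non-PV PSD-95 integrals)
  norm2 <- normalize_pv_ratios(syn, method = "ratio_of_means")
  expect_equal(norm2$normalized_glun1_density[1], 2)

  # a dendrite overlapping no synapse: zero count and density
  pl2 <- cbind(x_um = c(1, 4), y_um = c(9, 9))
  d2 <- list(dendrite_annotation("d2", pl2,
                                 synaptiq:::polyline_mask(pl2, dims, px_nm, 0.5)))
  res2 <- pv_dendrite_metrics(lm, d2, channels = list(GluN1 = mk(50)),
                              psd95 = mk(100), background_radius_px = 2)
  expect_equal(res2$dendrites$synapse_count, 0L)
  expect_equal(res2$dendrites$synapses_per_um, 0)
  expect_false(any(res2$synapses$on_pv_dendrite))

  # myelinated-axon annotations are ignored
  d3 <- list(dendrite_annotation("ax", pl, mask, is_myelinated_axon = TRUE))
  res3 <- pv_dendrite_metrics(lm, d3, channels = list(GluN1 = mk(50)),
                              psd95 = mk(100), background_radius_px = 2)
  expect_equal(nrow(res3$dendrites), 0)
})

test_that("somatic PV metrics subtract the neuropil background mean", {
  dims <- c(60, 60)
  lab <- matrix(0L, dims[1], dims[2]); lab[20:35, 20:35] <- 1L
  lm <- label_map(lab, 500, "soma")
  pv <- matrix(20, dims[1], dims[2]); pv[lab == 1L] <- 100
  bgmask <- lab == 0L
  met <- somatic_pv_metrics(pv, lm, bgmask)
  expect_equal(met$somata$mean_intensity_bgsub, 80)
  expect_equal(met$background_mean, 20)
  expect_equal(met$soma_density_per_um2, 1 / (3600 * 0.25))

  # soma equal to background: zero
  pv2 <- matrix(20, dims[1], dims[2])
  met2 <- somatic_pv_metrics(pv2, lm, bgmask)
  expect_equal(met2$somata$mean_intensity_bgsub, 0)

  expect_error(somatic_pv_metrics(pv, lm, matrix(FALSE, dims[1], dims[2])),
               "empty background")
})
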