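#' Configuration for the synthetic cohort generator
#'
#' Builds the full parameter set of the synthetic-microscopy generator. The
#' defaults encode the study conditions the pipeline is meant to analyse:
#' 9 control / 6 schizophrenia subjects; Layer-2 confocal fields of
#' 70 x 210 um at 100 nm/px with PSD-95 puncta at 0.15 um^-2; STED fields at
#' 20 nm/px with mean synaptic area 0.11 um^2, en-face fraction 196/264, and
#' Munc13-1 nanocluster counts linear in area with population mean 3.4
#' (minimum inter-cluster spacing 60 nm); deeper-layer fields at 0.23 um^-2
#' with PV-positive dendrites carrying 0.87 synapses/um whose synapses have
#' 122/192-scaled PSD-95 and receptor/PSD-95 ratios elevated relative to the
#' surrounding population (control subject-mean multipliers: AMPAR 1.72,
#' GluN1 1.60, GluN2B 1.72; schizophrenia: 1.54, 1.30, 1.43); and somatic PV
#' intensities of 1,362 (control) vs 955 (schizophrenia) AU. Images carry
#' Poisson shot noise plus Gaussian read noise and a Gaussian PSF (sigma
#' 130 nm confocal, 17 nm STED).
#'
#' @param seed integer master seed; every generated pixel is a deterministic
#'   function of it.
#' @param ... named overrides of nested defaults, e.g.
#'   `confocal = list(density_per_um2 = 0.2)`.
#' @return Nested list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    subjects = list(n_control = 9L, n_case = 6L),
    confocal = list(
      field_um = c(70, 210), pixel_size_nm = 100, psf_sigma_nm = 130,
      background = 20, read_noise = 2,
      density_per_um2 = 0.15, min_separation_um = 0.6,
      mean_area_um2 = 0.12, area_sdlog = 0.35,
      en_face_fraction = 196 / 264, side_view_width_um = 0.15,
      amplitude_mean = 300, amplitude_sdlog = 0.25,
      paired_channel = "GluA2", paired_ratio_mean = 0.8,
      subject_sdlog = 0.10, reaction_gain_sdlog = 0.15
    ),
    sted = list(
      field_um = c(10, 10), pixel_size_nm = 20, psf_sigma_nm = 17,
      background = 8, read_noise = 1,
      density_per_um2 = 0.12, min_separation_um = 0.9, margin_um = 0.7,
      mean_area_um2 = 0.11, area_sdlog = 0.5,
      en_face_fraction = 196 / 264, side_view_width_um = 0.12,
      psd95_amplitude_mean = 40, psd95_amplitude_sdlog = 0.3,
      nanocluster = list(
        k_per_um2 = 3.4 / 0.11, min_spacing_nm = 60, sigma_nm = 15,
        peak_mean = 60, peak_sdlog = 0.3, side_view_offset_nm = 40
      )
    ),
    pv_dendrite = list(
      n_control = 7L, n_case = 6L, fields_per_subject = 3L,
      field_um = c(40, 40), pixel_size_nm = 100, psf_sigma_nm = 130,
      background = 6, read_noise = 1,
      nonpv_density_per_um2 = 0.23, min_separation_um = 0.5,
      mean_area_um2 = 0.12, area_sdlog = 0.35,
      dendrites_per_field = 2L, dendrite_length_um = c(20, 35),
      dendrite_halfwidth_um = 0.5, synapses_per_um = 0.87,
      dendrite_exclusion_um = 0.7,
      psd95_integral_mean = 4800, psd95_integral_sdlog = 0.4,
      pv_psd95_scale = 122 / 192,
      base_ratio = c(AMPAR = 0.40, GluN1 = 0.35, GluN2B = 0.45),
      ratio_sdlog = 0.25,
      pv_mult_control = c(AMPAR = 1.72, GluN1 = 1.60, GluN2B = 1.72),
      pv_mult_control_sd = c(AMPAR = 0.14, GluN1 = 0.15, GluN2B = 0.25),
      pv_mult_case = c(AMPAR = 1.54, GluN1 = 1.30, GluN2B = 1.43),
      pv_mult_case_sd = c(AMPAR = 0.25, GluN1 = 0.19, GluN2B = 0.21)
    ),
    pv_soma = list(
      field_um = c(200, 400), pixel_size_nm = 500, psf_sigma_nm = 400,
      background = 300, read_noise = 5,
      somata_per_field_mean = 5, soma_diameter_um = c(mean = 15, sd = 2),
      intensity_control = c(mean = 1362, sd = 151),
      intensity_case = c(mean = 955, sd = 265),
      soma_sdlog = 0.12
    ),
    detect = list(
      prominence_confocal = 5, prominence_sted_psd95 = 10,
      prominence_munc = 10, blur_radius_px = 2, rolling_ball_radius_px = 7,
      ar_threshold = 2.7, dilate_px = 3L, psd95_min_integral = 10
    ),
    covariates = list(age_range = c(55, 85), pmi_mean = 3.3, pmi_sd = 0.7)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      utils::modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  }
  structure(cfg, class = "generator_config")
}

# Mean-parameterised lognormal draws: E[X] = mean.
rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Deterministic per-field seed below 2^31.
field_seed <- function(seed, subject_index, field_index, salt = 0L) {
  as.integer((as.numeric(seed) * 1000003 + subject_index * 10007 +
                field_index * 101 + salt * 13) %% 2147483647)
}

#' Subject roster with demographic covariates
#'
#' @param config a `generator_config`.
#' @param n_control,n_case subject counts (default from `config$subjects`).
#' @return data.frame `subject_id, condition, age_years, gender, pmi_hours`.
#' @export
subject_roster <- function(config, n_control = NULL, n_case = NULL) {
  n_control <- n_control %||% config$subjects$n_control
  n_case <- n_case %||% config$subjects$n_case
  set.seed(field_seed(config$seed, 0L, 0L, salt = 7L))
  n <- n_control + n_case
  data.frame(
    subject_id = c(sprintf("CON%02d", seq_len(n_control)),
                   sprintf("SCZ%02d", seq_len(n_case))),
    condition = rep(c("control", "schizophrenia"), c(n_control, n_case)),
    age_years = round(stats::runif(n, config$covariates$age_range[1],
                                   config$covariates$age_range[2])),
    gender = sample(c("male", "female"), n, replace = TRUE),
    pmi_hours = round(stats::rnorm(n, config$covariates$pmi_mean,
                                   config$covariates$pmi_sd), 1)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- low-level rendering ----------------------------------------------------

# Rasterise a rotated filled ellipse; returns linear pixel indices.
ellipse_indices <- function(dim_px, px_um, x_um, y_um, a_um, b_um, theta) {
  # bounding box
  ext <- max(a_um, b_um)
  c0 <- max(1L, floor((x_um - ext) / px_um)); c1 <- min(dim_px[2], ceiling((x_um + ext) / px_um) + 1L)
  r0 <- max(1L, floor((y_um - ext) / px_um)); r1 <- min(dim_px[1], ceiling((y_um + ext) / px_um) + 1L)
  if (c1 < c0 || r1 < r0) return(integer(0))
  cols <- c0:c1; rows <- r0:r1
  cx <- (cols - 0.5) * px_um - x_um
  cy <- (rows - 0.5) * px_um - y_um
  ct <- cos(theta); st <- sin(theta)
  # rotated coordinates for the row x col grid
  U <- outer(cy, cx, function(yy, xx) xx * ct + yy * st)
  V <- outer(cy, cx, function(yy, xx) -xx * st + yy * ct)
  inside <- (U / a_um)^2 + (V / b_um)^2 <= 1
  idx <- which(inside)
  if (length(idx) == 0) {
    # sub-pixel object: use the nearest pixel so every object renders
    rr <- min(max(round(y_um / px_um + 0.5), 1), dim_px[1])
    cc <- min(max(round(x_um / px_um + 0.5), 1), dim_px[2])
    return((cc - 1L) * dim_px[1] + rr)
  }
  rr <- rows[(idx - 1L) %% length(rows) + 1L]
  cc <- cols[(idx - 1L) %/% length(rows) + 1L]
  (cc - 1L) * dim_px[1] + rr
}

# Add a Gaussian spot of the given integral to a canvas.
add_gaussian_spot <- function(canvas, px_um, x_um, y_um, integral, sigma_um) {
  ext <- 4 * sigma_um
  nr <- nrow(canvas); nc <- ncol(canvas)
  c0 <- max(1L, floor((x_um - ext) / px_um)); c1 <- min(nc, ceiling((x_um + ext) / px_um) + 1L)
  r0 <- max(1L, floor((y_um - ext) / px_um)); r1 <- min(nr, ceiling((y_um + ext) / px_um) + 1L)
  if (c1 < c0 || r1 < r0) return(canvas)
  cols <- c0:c1; rows <- r0:r1
  gx <- stats::dnorm((cols - 0.5) * px_um - x_um, sd = sigma_um)
  gy <- stats::dnorm((rows - 0.5) * px_um - y_um, sd = sigma_um)
  patch <- outer(gy, gx) * px_um^2 * integral
  canvas[rows, cols] <- canvas[rows, cols] + patch
  canvas
}

# Dart-throwing placement of n points with a hard minimum separation.
place_points <- function(n, width_um, height_um, min_sep_um, margin_um = 0,
                         max_tries = 200L) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      x <- stats::runif(1, margin_um, width_um - margin_um)
      y <- stats::runif(1, margin_um, height_um - margin_um)
      if (i == 1 || all((xs[seq_len(i - 1)] - x)^2 +
                          (ys[seq_len(i - 1)] - y)^2 >= min_sep_um^2)) {
        xs[i] <- x; ys[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("place_points: density too high to respect the minimum separation")
  }
  cbind(x = xs, y = ys)
}

# Poisson shot noise + Gaussian read noise on an ideal canvas.
apply_noise <- function(canvas, read_noise) {
  n <- length(canvas)
  noisy <- stats::rpois(n, pmax(canvas, 0)) +
    stats::rnorm(n, 0, read_noise)
  matrix(pmax(noisy, 0), nrow(canvas), ncol(canvas))
}

# Above-half-max footprint area (um^2) of a blurred uniform ellipse,
# memoised on quantised semi-axes. This is the ground-truth "area" the
# detection pipeline is compared against.
half_max_area_cache <- new.env(parent = emptyenv())
half_max_area_um2 <- function(a_um, b_um, psf_sigma_um, px_um) {
  key <- sprintf("%.3f|%.3f|%.3f|%.4f",
                 round(a_um, 3), round(b_um, 3), psf_sigma_um, px_um)
  hit <- half_max_area_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- 4 * psf_sigma_um + px_um
  w <- 2 * (a_um + pad); h <- 2 * (b_um + pad)
  dims <- c(ceiling(h / px_um), ceiling(w / px_um))
  canvas <- matrix(0, dims[1], dims[2])
  idx <- ellipse_indices(dims, px_um, w / 2, h / 2, a_um, b_um, 0)
  canvas[idx] <- 1
  bl <- plane_pixels(gaussian_blur(canvas, psf_sigma_um / px_um))
  area <- sum(bl >= max(bl) / 2) * px_um^2
  half_max_area_cache[[key]] <- area
  area
}

# Draw synapse geometry: positions, view class, areas, ellipse axes, angle.
draw_synapse_geometry <- function(n, mcfg, px_um) {
  if (n == 0) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), view = character(0),
                      a_um = numeric(0), b_um = numeric(0),
                      theta = numeric(0)))
  }
  pos <- place_points(n, mcfg$field_um[1], mcfg$field_um[2],
                      mcfg$min_separation_um, margin_um = mcfg$margin_um %||% 0)
  area <- rlnorm_mean(n, mcfg$mean_area_um2, mcfg$area_sdlog)
  view <- ifelse(stats::runif(n) < mcfg$en_face_fraction, "en_face", "side_view")
  q <- stats::runif(n, 1, 1.8)                  # en-face axis ratio
  a <- ifelse(view == "en_face", sqrt(area * q / pi),
              area / (pi * mcfg$side_view_width_um / 2))
  b <- ifelse(view == "en_face", sqrt(area / (pi * q)),
              mcfg$side_view_width_um / 2)
  data.frame(x_um = pos[, "x"], y_um = pos[, "y"], area_um2 = area,
             view = view, a_um = a, b_um = b,
             theta = stats::runif(n, 0, pi))
}

# Render one channel from per-synapse integrals over shared geometry;
# returns list(pixels, integral_rendered).
render_channel <- function(dims, px_um, geom, integrals, psf_sigma_um,
                           background, read_noise, noise = TRUE) {
  canvas <- matrix(0, dims[1], dims[2])
  rendered <- numeric(nrow(geom))
  for (i in seq_len(nrow(geom))) {
    idx <- ellipse_indices(dims, px_um, geom$x_um[i], geom$y_um[i],
                           geom$a_um[i], geom$b_um[i], geom$theta[i])
    canvas[idx] <- canvas[idx] + integrals[i] / length(idx)
    rendered[i] <- integrals[i]
  }
  ideal <- plane_pixels(gaussian_blur(canvas, psf_sigma_um / px_um)) + background
  px <- if (noise) apply_noise(ideal, read_noise) else ideal
  list(pixels = px, rendered = rendered, ideal = ideal)
}

#' Simulate one multi-channel field with ground truth
#'
#' Renders one synthetic field of the requested modality and returns the
#' channel images together with an exhaustive ground-truth table of every
#' planted object. The same `(config, subject, field_index)` triple always
#' produces bit-identical output.
#'
#' @param config a `generator_config`.
#' @param subject one row of [subject_roster()] (or a list with
#'   `subject_id`, `condition` and a numeric `index`).
#' @param field_index integer field number within the subject.
#' @param modality `"confocal_layer2"`, `"sted_nanocluster"`,
#'   `"pv_dendrite"` or `"pv_soma"`.
#' @param noise render with Poisson + read noise (default `TRUE`).
#' @return List with `channels` (named list of [image_plane()]s) and `truth`
#'   (list of data.frames; always `synapses` or `somata`, plus `clusters` /
#'   `dendrites` where applicable).
#' @export
simulate_field <- function(config, subject, field_index,
                           modality = c("confocal_layer2", "sted_nanocluster",
                                        "pv_dendrite", "pv_soma"),
                           noise = TRUE) {
  modality <- match.arg(modality)
  sidx <- subject$index %||% match(subject$subject_id,
                                   subject_roster(config)$subject_id)
  if (is.na(sidx)) sidx <- 1L
  set.seed(field_seed(config$seed, sidx, field_index,
                      salt = match(modality, c("confocal_layer2",
                                               "sted_nanocluster",
                                               "pv_dendrite", "pv_soma"))))
  switch(modality,
         confocal_layer2 = sim_layer2_field(config, subject, field_index, noise),
         sted_nanocluster = sim_sted_field(config, subject, field_index, noise),
         pv_dendrite = sim_pv_dendrite_field(config, subject, field_index, noise),
         pv_soma = sim_pv_soma_field(config, subject, field_index, noise))
}

mk_plane <- function(px, px_nm, channel, subject, field_index) {
  image_plane(px, pixel_size_nm = px_nm, channel = channel,
              field_id = sprintf("%s_f%02d", subject$subject_id, field_index),
              subject_id = subject$subject_id, condition = subject$condition)
}

sim_layer2_field <- function(config, subject, field_index, noise) {
  m <- config$confocal
  px_um <- m$pixel_size_nm / 1000
  dims <- c(round(m$field_um[2] / px_um), round(m$field_um[1] / px_um))
  n <- stats::rpois(1, m$density_per_um2 * prod(m$field_um))
  geom <- draw_synapse_geometry(n, m, px_um)
  subj_gain <- rlnorm_mean(1, 1, m$subject_sdlog)
  amp <- rlnorm_mean(n, m$amplitude_mean, m$amplitude_sdlog) * subj_gain
  # PSD-95 integral = amplitude density x drawn pixel area
  npx <- pmax(geom$area_um2 / px_um^2, 1)
  psd_int <- amp * npx
  psd <- render_channel(dims, px_um, geom, psd_int, m$psf_sigma_nm / 1000,
                        m$background, m$read_noise, noise)
  paired_int <- psd_int * rlnorm_mean(n, m$paired_ratio_mean, 0.3)
  paired <- render_channel(dims, px_um, geom, paired_int,
                           m$psf_sigma_nm / 1000, m$background, m$read_noise,
                           noise)
  truth <- cbind(
    geom,
    data.frame(object_id = seq_len(max(n, 0)),
               psd95_integral = psd_int, paired_integral = paired_int,
               truth_area_um2 = vapply(seq_len(nrow(geom)), function(i)
                 half_max_area_um2(geom$a_um[i], geom$b_um[i],
                                   m$psf_sigma_nm / 1000, px_um), numeric(1)),
               subject_id = subject$subject_id,
               condition = subject$condition, field_index = field_index))
  list(channels = list(
    PSD95 = mk_plane(psd$pixels, m$pixel_size_nm, "PSD95", subject, field_index),
    paired = mk_plane(paired$pixels, m$pixel_size_nm, m$paired_channel,
                      subject, field_index)),
    truth = list(synapses = truth))
}

# place nanoclusters inside a synapse footprint with a hard minimum spacing
place_clusters <- function(k, geom_row, min_spacing_um, offset_um = 0) {
  if (k == 0) return(cbind(x = numeric(0), y = numeric(0)))
  ct <- cos(geom_row$theta); st <- sin(geom_row$theta)
  xs <- numeric(k); ys <- numeric(k)
  for (i in seq_len(k)) {
    best <- NULL; best_d <- -1
    for (t in seq_len(100L)) {
      # uniform in the ellipse (in its own frame)
      repeat {
        u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
        if (u^2 + v^2 <= 1) break
      }
      lx <- u * geom_row$a_um
      ly <- v * geom_row$b_um + offset_um
      x <- geom_row$x_um + lx * ct - ly * st
      y <- geom_row$y_um + lx * st + ly * ct
      d <- if (i == 1) Inf else
        sqrt(min((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2))
      if (d >= min_spacing_um) { best <- c(x, y); break }
      if (d > best_d) { best_d <- d; best <- c(x, y) }
    }
    xs[i] <- best[1]; ys[i] <- best[2]
  }
  cbind(x = xs, y = ys)
}

sim_sted_field <- function(config, subject, field_index, noise) {
  m <- config$sted
  nano <- m$nanocluster
  px_um <- m$pixel_size_nm / 1000
  dims <- c(round(m$field_um[2] / px_um), round(m$field_um[1] / px_um))
  n <- stats::rpois(1, m$density_per_um2 * prod(m$field_um))
  geom <- draw_synapse_geometry(n, m, px_um)
  psd_amp <- rlnorm_mean(n, m$psd95_amplitude_mean, m$psd95_amplitude_sdlog)
  npx <- pmax(geom$area_um2 / px_um^2, 1)
  psd_int <- psd_amp * npx
  psd <- render_channel(dims, px_um, geom, psd_int, m$psf_sigma_nm / 1000,
                        m$background, m$read_noise, noise)
  # Munc13-1: nanoclusters, count Poisson with mean linear in area
  sigma_tot_um <- sqrt(nano$sigma_nm^2 + m$psf_sigma_nm^2) / 1000
  counts <- stats::rpois(n, nano$k_per_um2 * geom$area_um2)
  munc <- matrix(0, dims[1], dims[2])
  cl_rows <- vector("list", n)
  for (i in seq_len(n)) {
    off <- if (geom$view[i] == "side_view")
      nano$side_view_offset_nm / 1000 else 0
    pts <- place_clusters(counts[i], geom[i, ], nano$min_spacing_nm / 1000,
                          offset_um = off)
    if (nrow(pts) > 0) {
      peaks <- rlnorm_mean(nrow(pts), nano$peak_mean, nano$peak_sdlog)
      ints <- peaks * 2 * pi * (sigma_tot_um / px_um)^2
      for (jj in seq_len(nrow(pts)))
        munc <- add_gaussian_spot(munc, px_um, pts[jj, 1], pts[jj, 2],
                                  ints[jj], nano$sigma_nm / 1000)
      cl_rows[[i]] <- data.frame(object_id = i, cluster_index = seq_len(nrow(pts)),
                                 x_um = pts[, 1], y_um = pts[, 2],
                                 peak = peaks)
    }
  }
  munc_ideal <- plane_pixels(gaussian_blur(munc, m$psf_sigma_nm / 1000 / px_um)) +
    m$background
  munc_px <- if (noise) apply_noise(munc_ideal, m$read_noise) else munc_ideal
  truth_syn <- cbind(
    geom,
    data.frame(object_id = seq_len(max(n, 0)), psd95_integral = psd_int,
               nanocluster_count = counts,
               truth_area_um2 = vapply(seq_len(nrow(geom)), function(i)
                 half_max_area_um2(geom$a_um[i], geom$b_um[i],
                                   m$psf_sigma_nm / 1000, px_um), numeric(1)),
               subject_id = subject$subject_id, condition = subject$condition,
               field_index = field_index))
  clusters <- if (n > 0) do.call(rbind, cl_rows[!vapply(cl_rows, is.null, TRUE)])
  list(channels = list(
    PSD95 = mk_plane(psd$pixels, m$pixel_size_nm, "PSD95", subject, field_index),
    Munc13 = mk_plane(munc_px, m$pixel_size_nm, "Munc13-1", subject, field_index)),
    truth = list(synapses = truth_syn,
                 clusters = clusters %||% data.frame()))
}

# random smooth dendrite polyline across the field
draw_dendrite_polyline <- function(field_um, length_um) {
  margin <- 2
  start <- c(stats::runif(1, margin, field_um[1] - margin),
             stats::runif(1, margin, field_um[2] - margin))
  ang <- stats::runif(1, 0, 2 * pi)
  step <- 2
  nseg <- ceiling(length_um / step)
  pts <- matrix(NA_real_, nseg + 1, 2)
  pts[1, ] <- start
  for (k in seq_len(nseg)) {
    ang <- ang + stats::rnorm(1, 0, 0.15)
    nxt <- pts[k, ] + step * c(cos(ang), sin(ang))
    nxt <- pmin(pmax(nxt, margin), field_um - margin)
    pts[k + 1, ] <- nxt
  }
  pts
}

sim_pv_dendrite_field <- function(config, subject, field_index, noise) {
  m <- config$pv_dendrite
  px_um <- m$pixel_size_nm / 1000
  dims <- c(round(m$field_um[2] / px_um), round(m$field_um[1] / px_um))
  chans <- names(m$base_ratio)
  is_control <- identical(subject$condition, "control")
  # subject-level multipliers: one draw per subject, shared across fields
  set.seed(field_seed(config$seed, subject$index %||% 1L, 0L, salt = 31L))
  mu <- if (is_control) m$pv_mult_control else m$pv_mult_case
  sdv <- if (is_control) m$pv_mult_control_sd else m$pv_mult_case_sd
  subj_mult <- pmax(stats::rnorm(length(chans), mu, sdv), 0.2)
  names(subj_mult) <- chans
  set.seed(field_seed(config$seed, subject$index %||% 1L, field_index, salt = 3L))

  # dendrites
  dend <- lapply(seq_len(m$dendrites_per_field), function(d) {
    len <- stats::runif(1, m$dendrite_length_um[1], m$dendrite_length_um[2])
    pl <- draw_dendrite_polyline(m$field_um, len)
    dendrite_annotation(
      dendrite_id = sprintf("%s_f%02d_d%d", subject$subject_id, field_index, d),
      polyline = pl,
      mask = polyline_mask(pl, dims, m$pixel_size_nm, m$dendrite_halfwidth_um),
      pv_positive = TRUE, is_myelinated_axon = FALSE)
  })

  # non-PV synapses; the dendrite tube plus a margin is excluded volume,
  # so surrounding synapses never sit on top of a PV dendrite
  n_bg <- stats::rpois(1, m$nonpv_density_per_um2 * prod(m$field_um))
  geom_bg <- draw_synapse_geometry(n_bg, utils::modifyList(
    m, list(en_face_fraction = 1, side_view_width_um = 0.15)), px_um)
  tube <- Reduce(`|`, lapply(dend, `[[`, "mask"))
  tube <- dilate_mask(tube, ceiling(m$dendrite_exclusion_um / px_um))
  bg_r <- pmin(pmax(round(geom_bg$y_um / px_um + 0.5), 1), dims[1])
  bg_c <- pmin(pmax(round(geom_bg$x_um / px_um + 0.5), 1), dims[2])
  geom_bg <- geom_bg[!tube[cbind(bg_r, bg_c)], , drop = FALSE]
  n_bg <- nrow(geom_bg)
  # PV synapses along dendrite polylines
  pv_rows <- lapply(dend, function(d) {
    len <- dendrite_length_um(d)
    # renewal process along the dendrite: inter-synapse gaps are a hard
    # minimum (synapse extent) plus an exponential tail, with the mean gap
    # set to 1 / linear density
    min_gap <- 0.45
    mean_gap <- 1 / m$synapses_per_um
    s <- numeric(0); pos <- 0
    repeat {
      pos <- pos + min_gap + stats::rexp(1, 1 / (mean_gap - min_gap))
      if (pos >= len) break
      s <- c(s, pos)
    }
    k <- length(s)
    if (k == 0) return(NULL)
    pl <- d$polyline
    seglen <- sqrt(rowSums(diff(pl)^2))
    cum <- c(0, cumsum(seglen))
    seg <- findInterval(s, cum, rightmost.closed = TRUE)
    seg <- pmin(pmax(seg, 1), nrow(pl) - 1)
    t <- (s - cum[seg]) / seglen[seg]
    base <- pl[seg, , drop = FALSE] + (pl[seg + 1, , drop = FALSE] -
                                         pl[seg, , drop = FALSE]) * t
    dir <- (pl[seg + 1, , drop = FALSE] - pl[seg, , drop = FALSE]) / seglen[seg]
    perp <- cbind(-dir[, 2], dir[, 1])
    off <- stats::runif(k, -0.3, 0.3)
    data.frame(x_um = base[, 1] + perp[, 1] * off,
               y_um = base[, 2] + perp[, 2] * off,
               dendrite_id = d$dendrite_id)
  })
  pv_pts <- do.call(rbind, pv_rows[!vapply(pv_rows, is.null, TRUE)])
  n_pv <- if (is.null(pv_pts)) 0L else nrow(pv_pts)
  geom_pv <- if (n_pv > 0) {
    g <- draw_synapse_geometry(n_pv, utils::modifyList(
      m, list(en_face_fraction = 1, side_view_width_um = 0.15,
              min_separation_um = 0.01)), px_um)
    g$x_um <- pv_pts$x_um; g$y_um <- pv_pts$y_um
    g
  } else NULL
  geom <- rbind(geom_bg, geom_pv)
  n <- nrow(geom)
  on_pv <- c(rep(FALSE, n_bg), rep(TRUE, n_pv))
  dend_id <- c(rep(NA_character_, n_bg),
               if (n_pv > 0) pv_pts$dendrite_id else character(0))

  psd_int <- rlnorm_mean(n, m$psd95_integral_mean, m$psd95_integral_sdlog)
  psd_int[on_pv] <- psd_int[on_pv] * m$pv_psd95_scale
  ratios <- sapply(chans, function(ch) {
    r <- rlnorm_mean(n, m$base_ratio[[ch]], m$ratio_sdlog)
    r[on_pv] <- r[on_pv] * subj_mult[[ch]]
    r
  })
  psf_um <- m$psf_sigma_nm / 1000
  psd <- render_channel(dims, px_um, geom, psd_int, psf_um, m$background,
                        m$read_noise, noise)
  channels <- list(PSD95 = mk_plane(psd$pixels, m$pixel_size_nm, "PSD95",
                                    subject, field_index))
  for (ch in chans) {
    rc <- render_channel(dims, px_um, geom, psd_int * ratios[, ch], psf_um,
                         m$background, m$read_noise, noise)
    channels[[ch]] <- mk_plane(rc$pixels, m$pixel_size_nm, ch, subject,
                               field_index)
  }
  # PV channel: bright dendrite tubes
  pv_canvas <- matrix(0, dims[1], dims[2])
  for (d in dend) pv_canvas[d$mask] <- pv_canvas[d$mask] + 150
  pv_ideal <- plane_pixels(gaussian_blur(pv_canvas, psf_um / px_um)) + m$background
  channels$PV <- mk_plane(if (noise) apply_noise(pv_ideal, m$read_noise)
                          else pv_ideal,
                          m$pixel_size_nm, "PV", subject, field_index)

  truth_syn <- cbind(geom, data.frame(
    object_id = seq_len(max(n, 0L)), on_pv_dendrite = on_pv,
    dendrite_id = dend_id, psd95_integral = psd_int))
  for (ch in chans) truth_syn[[paste0(tolower(ch), "_ratio")]] <- ratios[, ch]
  truth_syn$subject_id <- subject$subject_id
  truth_syn$condition <- subject$condition
  truth_syn$field_index <- field_index
  truth_dend <- data.frame(
    dendrite_id = vapply(dend, `[[`, "", "dendrite_id"),
    length_um = vapply(dend, dendrite_length_um, numeric(1)),
    pv_positive = TRUE, is_myelinated_axon = FALSE)
  list(channels = channels,
       truth = list(synapses = truth_syn, dendrites = truth_dend),
       dendrites = dend,
       subject_multipliers = subj_mult)
}

sim_pv_soma_field <- function(config, subject, field_index, noise) {
  m <- config$pv_soma
  px_um <- m$pixel_size_nm / 1000
  dims <- c(round(m$field_um[2] / px_um), round(m$field_um[1] / px_um))
  is_control <- identical(subject$condition, "control")
  # subject-level somatic intensity, one draw per subject
  set.seed(field_seed(config$seed, subject$index %||% 1L, 0L, salt = 41L))
  ic <- if (is_control) m$intensity_control else m$intensity_case
  subj_mean <- max(stats::rnorm(1, ic[["mean"]], ic[["sd"]]), 50)
  set.seed(field_seed(config$seed, subject$index %||% 1L, field_index, salt = 4L))
  k <- stats::rpois(1, m$somata_per_field_mean)
  canvas <- matrix(0, dims[1], dims[2])
  rows <- NULL
  if (k > 0) {
    pos <- place_points(k, m$field_um[1], m$field_um[2],
                        min_sep_um = 2.2 * m$soma_diameter_um[["mean"]],
                        margin_um = m$soma_diameter_um[["mean"]])
    dia <- pmax(stats::rnorm(k, m$soma_diameter_um[["mean"]],
                             m$soma_diameter_um[["sd"]]), 8)
    amp <- subj_mean * rlnorm_mean(k, 1, m$soma_sdlog)
    for (i in seq_len(k)) {
      idx <- ellipse_indices(dims, px_um, pos[i, 1], pos[i, 2],
                             dia[i] / 2, dia[i] / 2, 0)
      canvas[idx] <- canvas[idx] + amp[i]
    }
    rows <- data.frame(soma_index = seq_len(k), x_um = pos[, 1],
                       y_um = pos[, 2], diameter_um = dia,
                       amplitude = amp, subject_mean = subj_mean,
                       subject_id = subject$subject_id,
                       condition = subject$condition,
                       field_index = field_index)
  }
  ideal <- plane_pixels(gaussian_blur(canvas, m$psf_sigma_nm / 1000 / px_um)) +
    m$background
  px <- if (noise) apply_noise(ideal, m$read_noise) else ideal
  list(channels = list(PV = mk_plane(px, m$pixel_size_nm, "PV", subject,
                                     field_index)),
       truth = list(somata = rows %||% data.frame()))
}

#' Deterministic side-view synapse fixture for profile validation
#'
#' A zero-noise, STED-scale (20 nm/px) rendering of one side-view synapse
#' sequentially labelled in five channels, with the presynaptic channels
#' laterally offset from the PSD-95 bar by their known cleft distances:
#' GluA2 0 nm, Munc13-1 +40 nm, Bassoon +100 nm, VGLUT1 +220 nm (all integer
#' multiples of the 20 nm pixel grid). The fixture is regenerated
#' deterministically from code, so repeated calls are identical.
#'
#' @return List with `channels` (named `image_plane`s), `truth`
#'   (data.frame `channel, offset_nm`), `center` (box centre, um) and
#'   `direction` (long-axis unit vector pointing from post- to presynaptic
#'   side).
#' @export
make_sideview_fixture <- function() {
  px_nm <- 20
  px_um <- px_nm / 1000
  dims <- c(64L, 96L)                      # rows x cols
  offsets <- c(PSD95 = 0, GluA2 = 0, `Munc13-1` = 40, Bassoon = 100,
               VGLUT1 = 220)
  bar_len_um <- 0.4                        # along y
  bar_halfwidth_um <- 0.03                 # along x
  cx <- 0.79; cy <- 0.63                   # PSD-95 bar centre (a pixel centre), um
  planes <- lapply(names(offsets), function(ch) {
    canvas <- matrix(0, dims[1], dims[2])
    x0 <- cx + offsets[[ch]] / 1000
    idx <- ellipse_indices(dims, px_um, x0, cy, bar_halfwidth_um,
                           bar_len_um / 2, 0)
    canvas[idx] <- 100
    bl <- plane_pixels(gaussian_blur(canvas, 1))
    image_plane(bl, pixel_size_nm = px_nm, channel = ch,
                field_id = "fixture", subject_id = "fixture",
                condition = "fixture")
  })
  names(planes) <- names(offsets)
  list(channels = planes,
       truth = data.frame(channel = names(offsets),
                          offset_nm = as.numeric(offsets)),
       center = c(cx, cy), direction = c(1, 0))
}
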