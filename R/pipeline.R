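# Group stats need >= 2 subjects per condition; single-condition cohorts
# (e.g. control-only recovery runs) return NULL stats.
maybe_compare <- function(summaries, measures, families = NULL) {
  tab <- table(summaries$condition)
  if (length(tab) < 2 || any(tab < 2)) return(NULL)
  compare_groups(summaries, measures, families = families)
}

#' Quantify PSD-95 puncta in one Layer-2 confocal field
#'
#' Full single-field pass of the population analysis: synapse segmentation
#' (blur + Otsu + maxima splitting), rolling-ball background subtraction,
#' per-synapse PSD-95 and paired-channel intensities, morphometry, field
#' density and border-corrected mean NND.
#'
#' @param psd95 PSD-95 `image_plane`.
#' @param paired optional paired-protein `image_plane`.
#' @param params detection parameter list (defaults from
#'   `generator_config()$detect`): `prominence_confocal`, `blur_radius_px`,
#'   `rolling_ball_radius_px`.
#' @param reaction reaction label attached to every record.
#' @return List with `records` (per-synapse data.frame) and `field`
#'   (one-row [field_density()] summary).
#' @export
quantify_layer2_field <- function(psd95, paired = NULL,
                                  params = generator_config()$detect,
                                  reaction = "r1") {
  labels <- psd95_synapse_labels(psd95, params$prominence_confocal,
                                 blur_radius_px = params$blur_radius_px)
  props <- region_properties(labels)
  bg <- rolling_ball_background(plane_pixels(psd95),
                                params$rolling_ball_radius_px)
  psd_int <- per_synapse_intensity(labels, psd95, bg)
  records <- data.frame(
    synapse_id = sprintf("%s_s%05d", psd95$field_id, props$label),
    subject_id = psd95$subject_id, condition = psd95$condition,
    field_id = psd95$field_id, reaction = reaction,
    centroid_x_um = props$centroid_x_um, centroid_y_um = props$centroid_y_um,
    area_um2 = props$area_um2, aspect_ratio = props$aspect_ratio,
    touches_border = props$touches_border,
    psd95_mean = psd_int$mean, psd95_integral = psd_int$integral)
  if (!is.null(paired)) {
    pbg <- rolling_ball_background(plane_pixels(paired),
                                   params$rolling_ball_radius_px)
    pint <- per_synapse_intensity(labels, paired, pbg)
    records$channel_mean <- pint$mean
    records$channel_integral <- pint$integral
    records$channel <- paired$channel
  }
  list(records = records,
       field = field_density(labels, field_id = psd95$field_id),
       labels = labels)
}

#' Quantify Munc13-1 nanoclusters in one STED field
#'
#' STED-scale pass: PSD-95 segmentation, area and aspect-ratio morphometry,
#' en-face/side-view classification, and nanocluster counting inside 3-px
#' dilated synapse masks with one shared prominence.
#'
#' @param psd95,munc STED-scale `image_plane`s.
#' @param params detection parameters (`prominence_sted_psd95`,
#'   `prominence_munc`, `ar_threshold`, `dilate_px`, ...).
#' @return List with `records` (per-synapse data.frame incl.
#'   `nanocluster_count` and `view`) and `labels`.
#' @export
quantify_sted_field <- function(psd95, munc,
                                params = generator_config()$detect) {
  labels <- psd95_synapse_labels(psd95, params$prominence_sted_psd95,
                                 blur_radius_px = params$blur_radius_px)
  props <- region_properties(labels)
  counts <- count_nanoclusters(munc, labels, dilate_px = params$dilate_px,
                               prominence = params$prominence_munc)
  records <- data.frame(
    synapse_id = sprintf("%s_s%05d", psd95$field_id, props$label),
    subject_id = psd95$subject_id, condition = psd95$condition,
    field_id = psd95$field_id,
    centroid_x_um = props$centroid_x_um, centroid_y_um = props$centroid_y_um,
    area_um2 = props$area_um2, aspect_ratio = props$aspect_ratio,
    view = classify_view(props$aspect_ratio, params$ar_threshold),
    touches_border = props$touches_border,
    nanocluster_count = counts$nanocluster_count)
  list(records = records, labels = labels)
}

#' Quantify receptor content of synapses on PV dendrites in one field
#'
#' Deep-layer pass: summed-channel segmentation, PSD-95-integral filter,
#' receptor/PSD-95 ratios and PV-dendrite assignment.
#'
#' @param channels named list with `PSD95`, `AMPAR`, `GluN1` (and optionally
#'   `GluN2B`) `image_plane`s.
#' @param dendrites list of `dendrite_annotation`s.
#' @param params detection parameters.
#' @return [pv_dendrite_metrics()] output with provenance columns added.
#' @export
quantify_pv_field <- function(channels, dendrites,
                              params = generator_config()$detect) {
  labels <- summed_channel_labels(channels$PSD95, channels$AMPAR,
                                  channels$GluN1,
                                  params$prominence_confocal,
                                  blur_radius_px = params$blur_radius_px)
  labels <- filter_by_psd95_integral(labels, channels$PSD95,
                                     min_integral = params$psd95_min_integral)
  receptor <- channels[setdiff(names(channels), c("PSD95", "PV"))]
  out <- pv_dendrite_metrics(labels, dendrites, receptor, channels$PSD95)
  out$synapses$subject_id <- channels$PSD95$subject_id
  out$synapses$condition <- channels$PSD95$condition
  out$synapses$field_id <- channels$PSD95$field_id
  out$labels <- labels
  out
}

#' Run the Layer-2 population analysis on a simulated cohort
#'
#' Simulates (in memory) `fields_per_subject` confocal Layer-2 fields per
#' subject, quantifies each, and aggregates to subject level: mean density,
#' mean NND, mean synaptic area and mean PSD-95 intensity per subject,
#' followed by group comparisons.
#'
#' @param config a `generator_config`.
#' @param fields_per_subject fields per subject.
#' @param roster optional subject roster subset.
#' @return List with `fields`, `subjects` (per-subject summary) and `stats`
#'   ([compare_groups()] table).
#' @export
run_layer2_analysis <- function(config, fields_per_subject = 2L,
                                roster = NULL) {
  roster <- roster %||% subject_roster(config)
  fields <- list(); recs <- list()
  for (s in seq_len(nrow(roster))) {
    subject <- as.list(roster[s, ]); subject$index <- s
    for (f in seq_len(fields_per_subject)) {
      fld <- simulate_field(config, subject, f, "confocal_layer2")
      q <- quantify_layer2_field(fld$channels$PSD95, fld$channels$paired,
                                 params = config$detect)
      q$field$subject_id <- subject$subject_id
      q$field$condition <- subject$condition
      fields[[length(fields) + 1]] <- q$field
      recs[[length(recs) + 1]] <- q$records
    }
  }
  fields <- do.call(rbind, fields)
  recs <- do.call(rbind, recs)
  per_subj <- do.call(rbind, lapply(split(fields, fields$subject_id), function(g) {
    r <- recs[recs$subject_id == g$subject_id[1] & !recs$touches_border, ]
    data.frame(subject_id = g$subject_id[1], condition = g$condition[1],
               density_per_um2 = mean(g$density_per_um2),
               mean_nnd_um = mean(g$mean_nnd_um, na.rm = TRUE),
               area_um2 = mean(r$area_um2),
               psd95_mean = mean(r$psd95_mean),
               n_synapses = sum(g$synapse_count))
  }))
  rownames(per_subj) <- NULL
  stats_tab <- maybe_compare(per_subj,
                             c("density_per_um2", "mean_nnd_um",
                               "area_um2", "psd95_mean"))
  list(fields = fields, records = recs, subjects = per_subj, stats = stats_tab)
}

#' Run the STED nanocluster analysis on a simulated cohort
#'
#' @param config a `generator_config`.
#' @param fields_per_subject STED fields per subject.
#' @param roster optional roster subset.
#' @return List with `records` (pooled synapse records), `subjects`
#'   (per-subject mean counts by view class), `stats` and the pooled
#'   en-face area correlation (`correlation`).
#' @export
run_nanocluster_analysis <- function(config, fields_per_subject = 3L,
                                     roster = NULL) {
  roster <- roster %||% subject_roster(config)
  recs <- list()
  for (s in seq_len(nrow(roster))) {
    subject <- as.list(roster[s, ]); subject$index <- s
    for (f in seq_len(fields_per_subject)) {
      fld <- simulate_field(config, subject, f, "sted_nanocluster")
      q <- quantify_sted_field(fld$channels$PSD95, fld$channels$Munc13,
                               params = config$detect)
      recs[[length(recs) + 1]] <- q$records
    }
  }
  recs <- do.call(rbind, recs)
  per_subj <- do.call(rbind, lapply(split(recs, recs$subject_id), function(g) {
    data.frame(subject_id = g$subject_id[1], condition = g$condition[1],
               nanoclusters_all = mean(g$nanocluster_count),
               nanoclusters_en_face =
                 mean(g$nanocluster_count[g$view == "en_face"]),
               nanoclusters_side_view =
                 mean(g$nanocluster_count[g$view == "side_view"]),
               area_um2 = mean(g$area_um2[!g$touches_border]),
               n_synapses = nrow(g))
  }))
  rownames(per_subj) <- NULL
  stats_tab <- maybe_compare(per_subj,
                             c("nanoclusters_all", "nanoclusters_en_face",
                               "area_um2"))
  corr <- nanocluster_area_correlation(recs[!recs$touches_border, ])
  list(records = recs, subjects = per_subj, stats = stats_tab,
       correlation = corr)
}

#' Run the PV-dendrite receptor-density analysis on a simulated cohort
#'
#' Simulates deep-layer multi-channel fields with annotated PV dendrites,
#' quantifies receptor/PSD-95 ratios, normalises PV-synapse ratios to each
#' subject's surrounding population, and compares normalised densities
#' between groups with Holm correction over the receptor family.
#'
#' @param config a `generator_config`.
#' @param fields_per_subject fields per subject (default from config).
#' @param roster optional roster subset (defaults to the 7/6 PV-experiment
#'   roster).
#' @return List with `synapses`, `dendrites`, `subjects`, `stats`.
#' @export
run_pv_dendrite_analysis <- function(config, fields_per_subject = NULL,
                                     roster = NULL) {
  m <- config$pv_dendrite
  fields_per_subject <- fields_per_subject %||% m$fields_per_subject
  roster <- roster %||% subject_roster(config, m$n_control, m$n_case)
  syn <- list(); dend <- list()
  for (s in seq_len(nrow(roster))) {
    subject <- as.list(roster[s, ]); subject$index <- s
    for (f in seq_len(fields_per_subject)) {
      fld <- simulate_field(config, subject, f, "pv_dendrite")
      q <- quantify_pv_field(fld$channels, fld$dendrites,
                             params = config$detect)
      syn[[length(syn) + 1]] <- q$synapses
      if (nrow(q$dendrites) > 0) {
        q$dendrites$subject_id <- subject$subject_id
        q$dendrites$condition <- subject$condition
        dend[[length(dend) + 1]] <- q$dendrites
      }
    }
  }
  syn <- do.call(rbind, syn)
  dend <- do.call(rbind, dend)
  ratio_cols <- grep("_ratio$", names(syn), value = TRUE)
  norm <- do.call(rbind, lapply(split(syn, syn$subject_id),
                                normalize_pv_ratios))
  dens_cols <- grep("^normalized_.*_density$", names(norm), value = TRUE)
  per_subj <- do.call(rbind, lapply(split(norm, norm$subject_id), function(g) {
    pv <- g[g$on_pv_dendrite, , drop = FALSE]
    row <- data.frame(subject_id = g$subject_id[1], condition = g$condition[1],
                      n_pv_synapses = nrow(pv),
                      n_synapses = nrow(g),
                      psd95_integral_pv = mean(pv$psd95_integral),
                      psd95_integral_nonpv =
                        mean(g$psd95_integral[!g$on_pv_dendrite]))
    for (dc in dens_cols) row[[dc]] <- mean(pv[[dc]])
    d <- dend[dend$subject_id == g$subject_id[1], , drop = FALSE]
    row$synapses_per_um <- if (nrow(d)) sum(d$synapse_count) / sum(d$length_um)
                           else NA_real_
    row
  }))
  rownames(per_subj) <- NULL
  stats_tab <- maybe_compare(
    per_subj, c(dens_cols, "psd95_integral_pv", "synapses_per_um"),
    families = list(receptor_density = dens_cols))
  list(synapses = norm, dendrites = dend, subjects = per_subj,
       stats = stats_tab)
}

#' Run the somatic PV-intensity analysis on a simulated cohort
#'
#' @param config a `generator_config`.
#' @param fields_per_subject fields per subject.
#' @param roster optional roster (the somatic experiment used 8 control / 6
#'   schizophrenia subjects).
#' @return List with `somata`, `subjects`, `stats` and the percent reduction
#'   of the group means.
#' @export
run_pv_soma_analysis <- function(config, fields_per_subject = 3L,
                                 roster = NULL) {
  roster <- roster %||% subject_roster(config, 8L, 6L)
  rows <- list()
  for (s in seq_len(nrow(roster))) {
    subject <- as.list(roster[s, ]); subject$index <- s
    for (f in seq_len(fields_per_subject)) {
      fld <- simulate_field(config, subject, f, "pv_soma")
      pv <- fld$channels$PV
      som <- soma_labels(pv, min_area_um2 = 50)
      bgm <- neuropil_background_mask(pv)
      met <- somatic_pv_metrics(pv, som, bgm)
      if (nrow(met$somata) > 0) {
        met$somata$subject_id <- subject$subject_id
        met$somata$condition <- subject$condition
        rows[[length(rows) + 1]] <- met$somata
      }
    }
  }
  somata <- do.call(rbind, rows)
  per_subj <- do.call(rbind, lapply(split(somata, somata$subject_id), function(g)
    data.frame(subject_id = g$subject_id[1], condition = g$condition[1],
               somatic_pv = mean(g$mean_intensity_bgsub),
               n_somata = nrow(g))))
  rownames(per_subj) <- NULL
  stats_tab <- maybe_compare(per_subj, "somatic_pv")
  list(somata = somata, subjects = per_subj, stats = stats_tab,
       percent_reduction = if (is.null(stats_tab)) NA_real_ else
         percent_reduction(stats_tab$mean_control, stats_tab$mean_case))
}
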