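#' Write a synthetic cohort to disk
#'
#' Simulates `fields_per_subject` fields of one modality for every subject
#' and writes a self-describing cohort directory: one 32-bit float TIFF per
#' channel under `cohort/<subject>/`, a `metadata.csv` naming every image
#' with its subject, condition, field, channel and pixel size, ground-truth
#' CSVs under `truth/`, and a `manifest.yaml` listing every file with the
#' seed it derives from.
#'
#' @param config a `generator_config`.
#' @param dir output directory.
#' @param modality generator modality (see [simulate_field()]).
#' @param fields_per_subject fields per subject.
#' @param roster optional subject roster (defaults to [subject_roster()];
#'   the PV-dendrite modality defaults to its own 7/6 subject counts).
#' @param overwrite allow writing into an existing directory.
#' @return Invisibly, the manifest list.
#' @export
simulate_cohort <- function(config, dir, modality = "confocal_layer2",
                            fields_per_subject = 2L, roster = NULL,
                            overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("simulate_cohort: output directory exists; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  if (is.null(roster)) {
    roster <- if (modality == "pv_dendrite")
      subject_roster(config, config$pv_dendrite$n_control,
                     config$pv_dendrite$n_case)
    else subject_roster(config)
  }
  meta <- list(); truths <- list(); files <- character(0)
  for (s in seq_len(nrow(roster))) {
    subject <- as.list(roster[s, ])
    subject$index <- s
    sdir <- file.path(dir, subject$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (f in seq_len(fields_per_subject)) {
      fld <- simulate_field(config, subject, f, modality)
      for (ch in names(fld$channels)) {
        fn <- file.path(subject$subject_id,
                        sprintf("f%02d_%s.tiff", f, gsub("[^A-Za-z0-9]", "", ch)))
        sc <- write_image_plane(fld$channels[[ch]], file.path(dir, fn))
        files <- c(files, fn)
        meta[[length(meta) + 1]] <- data.frame(
          subject_id = subject$subject_id, condition = subject$condition,
          field_index = f, channel = ch, path = fn,
          pixel_size_nm = fld$channels[[ch]]$pixel_size_nm,
          intensity_scale = sc)
      }
      for (tn in names(fld$truth)) {
        tt <- fld$truth[[tn]]
        if (is.data.frame(tt) && nrow(tt) > 0) {
          truths[[tn]] <- c(truths[[tn]] %||% list(), list(tt))
        }
      }
      if (!is.null(fld$dendrites)) {
        ann <- do.call(rbind, lapply(fld$dendrites, function(d) {
          data.frame(dendrite_id = d$dendrite_id,
                     vertex_index = seq_len(nrow(d$polyline)),
                     x_um = d$polyline[, 1], y_um = d$polyline[, 2],
                     pv_positive = d$pv_positive,
                     is_myelinated_axon = d$is_myelinated_axon)
        }))
        fn <- file.path(subject$subject_id, sprintf("f%02d_dendrites.csv", f))
        utils::write.csv(ann, file.path(dir, fn), row.names = FALSE)
        files <- c(files, fn)
      }
    }
  }
  meta <- do.call(rbind, meta)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(roster, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (tn in names(truths)) {
    utils::write.csv(do.call(rbind, truths[[tn]]),
                     file.path(dir, "truth", paste0(tn, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    seed = config$seed, modality = modality,
    fields_per_subject = fields_per_subject,
    n_subjects = nrow(roster),
    files = as.list(c("metadata.csv", "subjects.csv",
                      file.path("truth", paste0(names(truths), ".csv")),
                      files)))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a cohort directory written by [simulate_cohort()]
#'
#' @param dir cohort directory.
#' @return List with `manifest`, `metadata`, `subjects`, `truth` (named list
#'   of data.frames) and a `read_plane(subject_id, field_index, channel)`
#'   closure returning an [image_plane()].
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  missing <- !file.exists(file.path(dir, unlist(manifest$files)))
  if (any(missing))
    stop("read_cohort: manifest lists missing file(s): ",
         paste(utils::head(unlist(manifest$files)[missing], 3), collapse = ", "))
  metadata <- utils::read.csv(file.path(dir, "metadata.csv"))
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"))
  truth_files <- list.files(file.path(dir, "truth"), full.names = TRUE)
  truth <- lapply(truth_files, utils::read.csv)
  names(truth) <- sub("[.]csv$", "", basename(truth_files))
  read_plane <- function(subject_id, field_index, channel) {
    row <- metadata[metadata$subject_id == subject_id &
                      metadata$field_index == field_index &
                      metadata$channel == channel, ]
    if (nrow(row) != 1) stop("read_cohort: no unique match for requested plane")
    read_image_plane(file.path(dir, row$path), row$pixel_size_nm,
                     intensity_scale = row$intensity_scale,
                     channel = channel, subject_id = subject_id,
                     field_id = sprintf("%s_f%02d", subject_id, field_index))
  }
  list(manifest = manifest, metadata = metadata, subjects = subjects,
       truth = truth, read_plane = read_plane, dir = dir)
}

#' Simulate subject-level summaries directly (no image rendering)
#'
#' Draws per-subject mean measures from the generator's subject-effect model
#' -- the route used for calibration suites (type-I error, power), where
#' hundreds of replicate cohorts are needed and the image-rendering stage
#' has already been validated separately.
#'
#' @param measures named list; each element is
#'   `list(mean_control=, sd_control=, mean_case=, sd_case=)`.
#' @param n_control,n_case subjects per group.
#' @param seed integer seed.
#' @return data.frame `subject_id, condition, age_years, gender, pmi_hours`
#'   plus one column per measure.
#' @export
simulate_subject_summaries <- function(measures, n_control = 9L, n_case = 6L,
                                       seed = 1L) {
  cfg <- generator_config(seed, subjects = list(n_control = n_control,
                                                n_case = n_case))
  roster <- subject_roster(cfg)
  set.seed(field_seed(seed, 1L, 1L, salt = 99L))
  for (mn in names(measures)) {
    m <- measures[[mn]]
    is_con <- roster$condition == "control"
    roster[[mn]] <- NA_real_
    roster[[mn]][is_con] <- stats::rnorm(sum(is_con), m$mean_control,
                                         m$sd_control)
    roster[[mn]][!is_con] <- stats::rnorm(sum(!is_con), m$mean_case,
                                          m$sd_case)
  }
  roster
}
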