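# Synthetic dataset plumbing: per-patient phantoms, rendered volumes on
# disk with a CSV manifest, and in-memory image sets for training.

# deterministic per-patient texture variation around the class defaults
patient_texture <- function(class_label, patient_seed) {
  tp <- phantom_texture(class_label)
  with_seed(patient_seed, {
    tp$mu_base <- tp$mu_base * runif(1, 0.9, 1.1)
    tp$refl_base <- tp$refl_base * runif(1, 0.9, 1.1)
    tp$surface_depth <- tp$surface_depth * runif(1, 0.8, 1.2)
    if (class_label == "IA") {
      tp$mu_levels <- tp$mu_levels * runif(1, 0.9, 1.1)
      tp$refl_levels <- tp$refl_levels * runif(1, 0.9, 1.1)
    }
    if (class_label == "NOR") {
      tp$n_spots <- max(10L, as.integer(round(tp$n_spots * runif(1, 0.8, 1.3))))
    }
  })
  tp
}

#' Patient-level train/test split
#'
#' Assigns whole patients to splits (never frames), with at least one
#' patient per split per class when possible.
#'
#' @param patients Patient id per observation.
#' @param train_frac Fraction of patients assigned to training
#'   (default 0.75).
#' @param seed Seed controlling the assignment.
#' @return Character vector `"train"`/`"test"` per observation.
#' @export
split_by_patient <- function(patients, train_frac = 0.75, seed = 1L) {
  u <- unique(as.character(patients))
  with_seed(seed, {
    n_train <- max(1L, min(length(u) - 1L, round(train_frac * length(u))))
    train_ids <- sample(u, n_train)
  })
  ifelse(as.character(patients) %in% train_ids, "train", "test")
}

#' Generate an in-memory synthetic image set
#'
#' Builds `n_per_class` model-ready images per class from
#' `patients_per_class` synthetic patients: every patient gets its own
#' texture variation and phantom, every image is an independent speckle
#' realization rendered at the model input size and min-max normalized.
#'
#' @param n_per_class Images per class.
#' @param patients_per_class Synthetic patients per class (default 10).
#' @param geometry An [scan_geometry()].
#' @param seed Master seed; the whole set is a pure function of it.
#' @param dim Image size `c(depth, width)` (default 128 x 218).
#' @param classes Classes to include (default all three).
#' @return List with `x` (depth x width x N array), `y` (labels),
#'   `patients` (patient ids) — frames of one patient are contiguous.
#' @export
synthetic_image_set <- function(n_per_class, patients_per_class = 10L,
                                geometry = scan_geometry(), seed = 1L,
                                dim = c(128L, 218L),
                                classes = GRADE_LEVELS) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  patients_per_class <- check_count(patients_per_class, "patients_per_class")
  x <- array(0, c(dim[1], dim[2], n_per_class * length(classes)))
  y <- character(0); patients <- character(0)
  i <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    per_pat <- diff(round(seq(0, n_per_class, length.out = patients_per_class + 1)))
    for (p in seq_len(patients_per_class)) {
      if (per_pat[p] == 0) next
      pid <- sprintf("%s_P%02d", cl, p)
      pseed <- seed + 1000L * ci + 10L * p
      ph <- generate_phantom(cl, geometry,
                             texture_params = patient_texture(cl, pseed),
                             seed = pseed)
      for (f in seq_len(per_pat[p])) {
        i <- i + 1L
        b <- render_bscan(ph, n_depth = dim[1], n_width = dim[2],
                          seed = pseed + 100000L + f)
        x[, , i] <- resize_normalize(b, dim = dim)
        y <- c(y, cl); patients <- c(patients, pid)
      }
    }
  }
  list(x = x, y = y, patients = patients)
}

#' Generate a synthetic raw dataset on disk
#'
#' Writes one volume file per (class, patient, volume): an array of
#' rendered B-scan frames (dB scale), a per-volume `metadata.json` with
#' placeholder patient details, and a `manifest.csv` with columns
#' `volume_id`, `class_label`, `patient_id`, `split`. Splits are assigned
#' per synthetic patient, never per frame. Deterministic for a fixed seed
#' (byte-identical manifest).
#'
#' @param n_volumes_per_class Volumes per class (>= 1).
#' @param geometry An [scan_geometry()].
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param frames_per_volume Frames rendered per volume (default 8; the
#'   physical system acquires 400, scaled down for desk use).
#' @param volumes_per_patient Volumes per synthetic patient (default 1).
#' @param train_frac Fraction of patients in the training split.
#' @param dim Frame size `c(depth, width)`.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, the manifest data frame.
#' @export
generate_dataset <- function(n_volumes_per_class,
                             geometry = scan_geometry(),
                             out_dir,
                             seed = 1L,
                             frames_per_volume = 8L,
                             volumes_per_patient = 1L,
                             train_frac = 0.75,
                             dim = c(128L, 218L),
                             overwrite = FALSE) {
  n_volumes_per_class <- check_count(n_volumes_per_class, "n_volumes_per_class")
  frames_per_volume <- check_count(frames_per_volume, "frames_per_volume")
  volumes_per_patient <- check_count(volumes_per_patient, "volumes_per_patient")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    oct_abort("output directory '", out_dir,
              "' exists and is not empty; pass overwrite = TRUE")
  }
  dir.create(file.path(out_dir, "volumes"), showWarnings = FALSE, recursive = TRUE)

  manifest <- data.frame()
  for (ci in seq_along(GRADE_LEVELS)) {
    cl <- GRADE_LEVELS[ci]
    n_pat <- ceiling(n_volumes_per_class / volumes_per_patient)
    pat_ids <- sprintf("%s_P%02d", cl, seq_len(n_pat))
    pat_split <- split_by_patient(pat_ids, train_frac, seed = seed + ci)
    v <- 0L
    for (p in seq_len(n_pat)) {
      pseed <- seed + 1000L * ci + 10L * p
      ph <- generate_phantom(cl, geometry,
                             texture_params = patient_texture(cl, pseed),
                             seed = pseed)
      n_here <- min(volumes_per_patient, n_volumes_per_class - v)
      for (k in seq_len(n_here)) {
        v <- v + 1L
        vol_id <- sprintf("%s_V%03d", cl, v)
        frames <- array(0, c(dim[1], dim[2], frames_per_volume))
        for (f in seq_len(frames_per_volume)) {
          frames[, , f] <- render_bscan(ph, n_depth = dim[1], n_width = dim[2],
                                        seed = pseed + 100000L * k + f)$image
        }
        saveRDS(list(frames = frames,
                     depth_pitch = geometry$depth_range * 1000 / dim[1],
                     lateral_pitch = geometry$lateral_range * 1000 / dim[2],
                     class_label = cl, patient_id = pat_ids[p]),
                file.path(out_dir, "volumes", paste0(vol_id, ".rds")))
        meta <- list(name = sprintf("Synthetic Patient %s", pat_ids[p]),
                     chart_number = sprintf("C%05d", 10000L + 100L * ci + p),
                     gender = c("F", "M")[1L + (p %% 2L)],
                     sample_number = k,
                     volume_number = v,
                     n_bscans = frames_per_volume)
        jsonlite::write_json(meta,
                             file.path(out_dir, "volumes", paste0(vol_id, ".json")),
                             auto_unbox = TRUE, pretty = TRUE)
        manifest <- rbind(manifest, data.frame(
          volume_id = vol_id, class_label = cl, patient_id = pat_ids[p],
          split = pat_split[p], stringsAsFactors = FALSE))
      }
    }
  }
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
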