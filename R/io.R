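#' Read and write ECG recordings as per-lead CSV
#'
#' The on-disk format is one CSV with a `time_s` column and one voltage
#' column (mV) per lead; ground truth, when present, travels in a JSON
#' sidecar.
#'
#' @param rec An [`ecg_recording`][simulate_ecg].
#' @param path CSV path.
#' @param truth_path Optional JSON path for the ground-truth sidecar.
#' @return `write_ecg_csv()` returns `path` invisibly; `read_ecg_csv()`
#'   returns an `ecg_recording` (with `truth = NULL` unless a sidecar is
#'   given).
#' @export
write_ecg_csv <- function(rec, path, truth_path = NULL) {
  qts_check(inherits(rec, "ecg_recording"), "invalid_parameter",
            "`rec` must be an ecg_recording")
  n <- nrow(rec$signals)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs_hz)
  for (lead in colnames(rec$signals)) df[[lead]] <- rec$signals[, lead]
  write.csv(df, path, row.names = FALSE)
  if (!is.null(truth_path)) {
    tr <- rec$truth
    tr$qt_ms <- as.list(tr$qt_ms)
    jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' @rdname write_ecg_csv
#' @param subject_id,timepoint Metadata to attach to the recording.
#' @param fs_hz Sampling rate; inferred from the `time_s` column when NULL.
#' @export
read_ecg_csv <- function(path, subject_id = "S01", timepoint = "admission",
                         fs_hz = NULL, truth_path = NULL) {
  df <- read.csv(path, check.names = FALSE)
  qts_check("time_s" %in% names(df) && ncol(df) >= 2, "invalid_parameter",
            "ECG CSV needs a `time_s` column plus one column per lead")
  if (is.null(fs_hz)) fs_hz <- 1 / median(diff(df$time_s))
  leads <- setdiff(names(df), "time_s")
  signals <- as.matrix(df[leads])
  truth <- if (!is.null(truth_path)) jsonlite::read_json(
    truth_path, simplifyVector = TRUE) else NULL
  structure(list(subject_id = subject_id, timepoint = timepoint,
                 fs_hz = fs_hz, leads = leads, signals = signals,
                 truth = truth),
            class = "ecg_recording")
}

nifti_path <- function(dir, name) file.path(dir, paste0(name, ".nii"))

write_mask_nifti <- function(mask, spacing, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
}

#' Read and write CMR studies as NIfTI volumes
#'
#' A study directory holds `t2w.nii` and `lge.nii` (signal intensity),
#' `myo_mask.nii` and `remote_mask.nii` (0/1 labels), and, for synthetic
#' studies, `truth_labels.nii` (0 background, 1 edema, 2 infarct, 3 MVO;
#' nested lesions carry the innermost label).  Voxel spacing is stored in
#' the NIfTI header.
#'
#' @param study A [`cmr_study`][simulate_cmr_phantom].
#' @param dir Directory to write into (created if needed).
#' @return `write_cmr_study()` returns `dir` invisibly; `read_cmr_study()`
#'   returns a `cmr_study`.
#' @export
write_cmr_study <- function(study, dir) {
  qts_check(inherits(study, "cmr_study"), "invalid_parameter",
            "`study` must be a cmr_study")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- study$spacing_mm
  for (nm in c("t2w", "lge")) {
    img <- RNifti::asNifti(study[[nm]])
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, nifti_path(dir, nm))
  }
  write_mask_nifti(study$myo_mask, sp, nifti_path(dir, "myo_mask"))
  write_mask_nifti(study$remote_mask, sp, nifti_path(dir, "remote_mask"))
  if (!is.null(study$truth)) {
    lab <- array(0L, dim(study$t2w))
    lab[study$truth$edema] <- 1L
    lab[study$truth$infarct] <- 2L
    lab[study$truth$mvo] <- 3L
    write_mask_nifti(lab > 0, sp, nifti_path(dir, "truth_any"))
    img <- RNifti::asNifti(lab); RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, nifti_path(dir, "truth_labels"))
  }
  invisible(dir)
}

#' @rdname write_cmr_study
#' @param subject_id Identifier for the loaded study.
#' @export
read_cmr_study <- function(dir, subject_id = basename(dir)) {
  need <- c("t2w", "lge", "myo_mask", "remote_mask")
  paths <- nifti_path(dir, need)
  qts_check(all(file.exists(paths)), "invalid_parameter",
            sprintf("missing NIfTI file(s) in %s", dir))
  t2w <- RNifti::readNifti(paths[1])
  sp <- RNifti::pixdim(t2w)[1:3]
  vols <- lapply(paths, function(p) {
    v <- RNifti::readNifti(p); array(as.numeric(v), dim(v))
  })
  truth <- NULL
  tl <- nifti_path(dir, "truth_labels")
  if (file.exists(tl)) {
    lab <- RNifti::readNifti(tl)
    lab <- array(as.integer(lab), dim(lab))
    truth <- list(edema = lab >= 1, infarct = lab >= 2, mvo = lab == 3)
  }
  structure(list(subject_id = subject_id, t2w = vols[[1]], lge = vols[[2]],
                 spacing_mm = as.numeric(sp),
                 myo_mask = vols[[3]] > 0.5, remote_mask = vols[[4]] > 0.5,
                 truth = truth),
            class = "cmr_study")
}

#' Read and write the cohort covariate table
#'
#' One row per subject; see [simulate_cohort()] for the column dictionary.
#'
#' @param table Cohort data frame.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(table, path) {
  qts_check(is.data.frame(table) && "subject_id" %in% names(table),
            "invalid_parameter", "cohort table needs a `subject_id` column")
  qts_check(!anyDuplicated(table$subject_id), "invalid_parameter",
            "duplicated subject ids in cohort table")
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  qts_check("subject_id" %in% names(tab), "invalid_parameter",
            "cohort CSV needs a `subject_id` column")
  qts_check(!anyDuplicated(tab$subject_id), "invalid_parameter",
            "duplicated subject ids in cohort CSV")
  tab
}
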