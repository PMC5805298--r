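#' Remote-myocardium signal statistics
#'
#' Mean and sample SD of the signal intensity over the remote reference ROI
#' (normal myocardium contralateral to the infarct), the reference for the
#' SD-threshold segmentation rules.
#'
#' @param volume Numeric array of signal intensities.
#' @param roi Logical array (same shape): the remote ROI.
#' @return List with `mean` and `sd` (sample SD; 0 when the ROI has a
#'   single voxel).
#' @export
remote_stats <- function(volume, roi) {
  qts_check(is.array(volume) && is.logical(roi) &&
              identical(dim(volume), dim(roi)),
            "invalid_parameter", "volume and ROI must share dimensions")
  v <- volume[roi]
  qts_check(length(v) >= 1, "empty_roi", "remote ROI is empty")
  s <- if (length(v) > 1) sd(v) else 0
  list(mean = mean(v), sd = s)
}

threshold_mask <- function(volume, myo_mask, stats, k) {
  qts_check(is.array(volume) && is.logical(myo_mask) &&
              identical(dim(volume), dim(myo_mask)),
            "invalid_parameter", "volume and mask must share dimensions")
  qts_check(is.list(stats) && is.finite(stats$mean) && is.finite(stats$sd) &&
              stats$sd >= 0, "invalid_parameter",
            "`stats` must come from remote_stats()")
  myo_mask & volume > stats$mean + k * stats$sd
}

#' Segment myocardial edema (area at risk) on T2-weighted images
#'
#' A myocardial voxel belongs to the area at risk when its signal intensity
#' strictly exceeds the remote mean by more than 2 remote SDs.
#'
#' @param volume T2-weighted signal-intensity array.
#' @param myo_mask Logical myocardial mask.
#' @param stats Remote statistics from [remote_stats()].
#' @return Logical mask of edematous myocardium.
#' @export
segment_edema <- function(volume, myo_mask, stats)
  threshold_mask(volume, myo_mask, stats, 2)

#' Segment infarcted myocardium on late gadolinium enhancement images
#'
#' A myocardial voxel is infarcted when its LGE signal intensity strictly
#' exceeds the remote mean by more than 5 remote SDs.  On any single image
#' this mask is a subset of the 2 SD rule applied to the same image.
#'
#' @inheritParams segment_edema
#' @param volume LGE signal-intensity array.
#' @return Logical mask of hyper-enhanced (infarcted) myocardium.
#' @export
segment_infarct <- function(volume, myo_mask, stats)
  threshold_mask(volume, myo_mask, stats, 5)

## 4-connected component labelling of a logical matrix (one slice).
label_components_2d <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nr <- nrow(m); cur <- 0L
  todo <- which(m)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start; lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      i <- ((v - 1L) %% nr) + 1L; j <- ((v - 1L) %/% nr) + 1L
      for (nb in c(if (i > 1) v - 1L, if (i < nr) v + 1L,
                   if (j > 1) v - nr, if (j < ncol(m)) v + nr)) {
        if (m[nb] && lab[nb] == 0L) { lab[nb] <- cur; queue <- c(queue, nb) }
      }
    }
  }
  lab
}

#' Detect microvascular obstruction inside the infarct
#'
#' Microvascular obstruction (MVO) is a hypo-enhanced core within infarcted
#' myocardium: here, per-slice 4-connected regions of voxels with LGE signal
#' at or below the remote mean whose entire in-slice neighbourhood lies in
#' the infarct mask.  Dark regions touching non-infarcted tissue (or the
#' volume edge) are not "within infarcted myocardium" and are excluded.
#'
#' @param volume LGE signal-intensity array.
#' @param infarct_mask Logical infarct mask from [segment_infarct()].
#' @param stats Remote statistics from [remote_stats()].
#' @return List: `mask` (logical MVO mask) and `present` (any MVO voxel).
#' @export
detect_mvo <- function(volume, infarct_mask, stats) {
  qts_check(is.array(volume) && is.logical(infarct_mask) &&
              identical(dim(volume), dim(infarct_mask)),
            "invalid_parameter", "volume and mask must share dimensions")
  d <- dim(volume)
  out <- array(FALSE, d)
  dark <- volume <= stats$mean
  for (s in seq_len(d[3])) {
    lab <- label_components_2d(dark[, , s])
    if (!any(lab > 0L)) next
    inf2 <- infarct_mask[, , s]
    for (k in seq_len(max(lab))) {
      cells <- which(lab == k, arr.ind = TRUE)
      ## in-slice 4-neighbourhood of the component
      nb <- rbind(cbind(cells[, 1] - 1L, cells[, 2]),
                  cbind(cells[, 1] + 1L, cells[, 2]),
                  cbind(cells[, 1], cells[, 2] - 1L),
                  cbind(cells[, 1], cells[, 2] + 1L))
      if (any(nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2]))
        next                      # touches the volume edge
      outside <- lab[nb] != k
      if (all(inf2[nb[outside, , drop = FALSE]])) {
        sl <- out[, , s]; sl[cells] <- TRUE; out[, , s] <- sl
      }
    }
  }
  list(mask = out, present = any(out))
}

#' Convert a voxel mask to tissue mass
#'
#' `mass = n_voxels * voxel_volume_mL * density`, with the voxel volume from
#' the spacing in mm (1 mL = 1000 mm^3) and myocardial density defaulting to
#' the standard 1.05 g/mL.
#'
#' @param mask Logical array.
#' @param spacing_mm Voxel spacing `c(row, col, slice)` in mm, all positive.
#' @param density_g_per_ml Tissue density, g/mL.
#' @return Mass in grams.
#' @examples
#' mask_mass(array(TRUE, c(10, 10, 10)), c(1.4, 2.2, 8))
#' @export
mask_mass <- function(mask, spacing_mm, density_g_per_ml = 1.05) {
  qts_check(is.logical(mask), "invalid_parameter", "`mask` must be logical")
  qts_check(is.numeric(spacing_mm) && length(spacing_mm) == 3 &&
              all(spacing_mm > 0), "invalid_parameter",
            "`spacing_mm` must be 3 positive numbers")
  check_number(density_g_per_ml, "density_g_per_ml", lower = 0,
               strict_lower = TRUE)
  sum(mask) * prod(spacing_mm) / 1000 * density_g_per_ml
}

#' Myocardial salvage index
#'
#' `MSI = (AAR - infarct) / AAR`: the fraction of the at-risk area that was
#' not irreversibly lost.  1 means full salvage (no enhancement), 0 means
#' the entire area at risk infarcted.  The ratio is clipped to \[0, 1\];
#' `infarct_g > aar_g` (a measurement inconsistency) clips to 0 with a
#' warning.
#'
#' @param aar_g Area-at-risk (edema) mass in grams; must be positive.
#' @param infarct_g Infarct (LGE) mass in grams; non-negative.
#' @return MSI as a fraction in \[0, 1\].
#' @examples
#' compute_msi(62, 59)  # 0.048...
#' compute_msi(30, 0)   # 1
#' @export
compute_msi <- function(aar_g, infarct_g) {
  qts_check(is.numeric(aar_g) && length(aar_g) == 1 && is.finite(aar_g),
            "invalid_parameter", "`aar_g` must be a single number")
  qts_check(aar_g > 0, "undefined_msi",
            "MSI undefined: area at risk is zero")
  check_number(infarct_g, "infarct_g", lower = 0)
  if (infarct_g > aar_g)
    warning("infarct mass exceeds area at risk; MSI clipped to 0")
  min(1, max(0, (aar_g - infarct_g) / aar_g))
}

#' Quantify one CMR study: area at risk, infarct, MVO and salvage index
#'
#' Runs the full tissue-quantification chain on a dual-contrast study:
#' remote statistics are measured separately on the T2-weighted and LGE
#' volumes, edema is segmented at the 2 SD threshold, infarct at the 5 SD
#' threshold, MVO as the dark core inside the infarct.  MVO voxels are
#' counted as part of the infarct mass (and reported separately, so the
#' opposite convention is recoverable).  Masses use the voxel spacing and a
#' myocardial density of 1.05 g/mL.
#'
#' @param study A [`cmr_study`][simulate_cmr_phantom] (or compatible list
#'   with `t2w`, `lge`, `myo_mask`, `remote_mask`, `spacing_mm`).
#' @param density_g_per_ml Myocardial density, g/mL.
#' @param include_mvo_in_infarct Count the MVO core inside the infarct mass
#'   (default TRUE).
#' @return Object of class `cmr_quantification`: masses in grams and %LV for
#'   AAR and LGE, MVO presence and mass, LV mass, MSI, plus the segmented
#'   masks and the remote statistics used.
#' @export
quantify_cmr <- function(study, density_g_per_ml = 1.05,
                         include_mvo_in_infarct = TRUE) {
  qts_check(is.list(study) && !is.null(study$t2w) && !is.null(study$lge) &&
              !is.null(study$myo_mask) && !is.null(study$remote_mask),
            "invalid_parameter", "`study` must be a cmr_study")
  sp <- study$spacing_mm
  st_t2 <- remote_stats(study$t2w, study$remote_mask)
  st_lge <- remote_stats(study$lge, study$remote_mask)

  edema <- segment_edema(study$t2w, study$myo_mask, st_t2)
  infarct <- segment_infarct(study$lge, study$myo_mask, st_lge)
  mvo <- detect_mvo(study$lge, infarct, st_lge)
  infarct_total <- if (include_mvo_in_infarct) infarct | mvo$mask else infarct

  lv_g <- mask_mass(study$myo_mask, sp, density_g_per_ml)
  aar_g <- mask_mass(edema, sp, density_g_per_ml)
  lge_g <- mask_mass(infarct_total, sp, density_g_per_ml)
  mvo_g <- mask_mass(mvo$mask, sp, density_g_per_ml)
  msi <- if (aar_g > 0) compute_msi(aar_g, lge_g) else NA_real_

  structure(list(subject_id = study$subject_id,
                 aar_g = aar_g, aar_pct = pct_of(aar_g, lv_g),
                 lge_g = lge_g, lge_pct = pct_of(lge_g, lv_g),
                 mvo_present = mvo$present, mvo_g = mvo_g,
                 lv_mass_g = lv_g, msi = msi,
                 masks = list(edema = edema, infarct = infarct_total,
                              mvo = mvo$mask),
                 remote = list(t2w = st_t2, lge = st_lge)),
            class = "cmr_quantification")
}

#' @export
print.cmr_quantification <- function(x, ...) {
  cat(sprintf("<cmr_quantification> subject %s\n", x$subject_id))
  cat(sprintf("  AAR %.1f g (%.1f%% LV), LGE %.1f g (%.1f%% LV)\n",
              x$aar_g, x$aar_pct, x$lge_g, x$lge_pct))
  cat(sprintf("  MVO %s (%.1f g), LV mass %.1f g, MSI %s\n",
              if (x$mvo_present) "present" else "absent", x$mvo_g,
              x$lv_mass_g,
              if (is.na(x$msi)) "undefined" else sprintf("%.2f", x$msi)))
  invisible(x)
}

#' @rdname quantify_cmr
#' @param x A `cmr_quantification` object.
#' @param ... Unused.
#' @export
as.data.frame.cmr_quantification <- function(x, ...) {
  data.frame(subject_id = x$subject_id, aar_g = x$aar_g,
             aar_pct = x$aar_pct, lge_g = x$lge_g, lge_pct = x$lge_pct,
             mvo_present = x$mvo_present, mvo_g = x$mvo_g,
             lv_mass_g = x$lv_mass_g, msi = x$msi)
}
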