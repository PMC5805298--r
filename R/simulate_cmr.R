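## Sector geometry helper: voxels of a short-axis annular sector.
## `dim` = c(rows, cols, slices); spacing in mm; radii in mm measured from
## the grid centre; `theta` an angular arc in degrees (may wrap past 360).
sector_mask <- function(dim, spacing_mm, radii_mm, theta_deg, slices) {
  qts_check(all(slices >= 1) && all(slices <= dim[3]), "invalid_parameter",
            "mask geometry exceeds grid: slice range outside volume")
  cx <- (dim[1] + 1) / 2; cy <- (dim[2] + 1) / 2
  x <- (seq_len(dim[1]) - cx) * spacing_mm[1]
  y <- (seq_len(dim[2]) - cy) * spacing_mm[2]
  qts_check(radii_mm[2] <= min(max(abs(x)), max(abs(y))), "invalid_parameter",
            "mask geometry exceeds grid: outer radius beyond field of view")
  r <- sqrt(outer(x^2, y^2, `+`))
  ang <- (atan2(outer(rep(1, dim[1]), y), outer(x, rep(1, dim[2]))) *
            180 / pi) %% 360
  span <- (theta_deg[2] - theta_deg[1]) %% 360
  if (span == 0) span <- 360
  in_arc <- ((ang - theta_deg[1]) %% 360) <= span
  disk <- r >= radii_mm[1] & r <= radii_mm[2] & in_arc
  m <- array(FALSE, dim)
  for (s in slices) m[, , s] <- disk
  m
}

#' Simulate a dual-contrast short-axis CMR phantom with known lesion masks
#'
#' Builds a voxel phantom of the left-ventricular myocardium as an annulus
#' on a stack of short-axis slices, with three nested lesions defined as
#' annular sectors: edema (the area at risk, bright on the T2-weighted
#' volume), infarct (bright on the late-gadolinium-enhancement volume,
#' contained in the edema sector) and an optional microvascular-obstruction
#' core (dark on LGE, contained in the infarct sector and kept away from
#' the wall surfaces so it is fully surrounded by enhanced tissue in-slice).
#'
#' Signal model: `SI = remote_mean + offset * remote_sd + N(0, noise_sd^2)`,
#' with lesion offsets expressed in nominal remote-SD units.  With
#' `noise_sd = 0` every lesion voxel sits exactly at its offset, so
#' threshold segmentation recovers the ground-truth masks voxel-exactly;
#' with the default `noise_sd = remote_sd` the remote ROI is distributed
#' `N(remote_mean, remote_sd^2)` as in real tissue.
#'
#' @param dim Grid size `c(rows, cols, slices)`.
#' @param spacing_mm Voxel spacing `c(row_mm, col_mm, slice_mm)`.
#' @param remote_mean,remote_sd Remote-myocardium signal intensity mean and
#'   nominal SD (arbitrary units).
#' @param edema_offset_sd,infarct_offset_sd,mvo_offset_sd Lesion offsets in
#'   remote-SD units; must exceed the 2 / 5 SD detection thresholds
#'   (`edema_offset_sd > 2`, `infarct_offset_sd > 5`, `mvo_offset_sd < 0`).
#' @param wall_radii_mm Inner/outer myocardial radii, mm.
#' @param edema_geom,infarct_geom,mvo_geom Lesion geometry lists with
#'   elements `theta` (degrees, arc), `slices`, and optionally `radii`
#'   (defaults to the full wall).  `infarct_geom`/`mvo_geom` may be `NULL`
#'   for no infarct / no MVO; masks must nest (MVO in infarct in edema).
#' @param remote_geom Remote-ROI geometry (contralateral normal wall).
#' @param noise_sd Additive Gaussian noise SD (same units as SI).
#' @param background Signal level outside the myocardium.
#' @param subject_id Identifier carried on the study.
#' @param seed Optional RNG seed (fixed seed reproduces the phantom).
#'
#' @return Object of class `cmr_study`: `t2w` and `lge` volumes (arrays),
#'   `spacing_mm`, `myo_mask`, `remote_mask`, and `truth` with the
#'   ground-truth `edema`, `infarct`, `mvo` masks (infarct includes the MVO
#'   core) and the generating parameters.
#' @export
simulate_cmr_phantom <- function(dim = c(64, 64, 6),
                                 spacing_mm = c(1.4, 2.2, 8),
                                 remote_mean = 100, remote_sd = 10,
                                 edema_offset_sd = 3, infarct_offset_sd = 7,
                                 mvo_offset_sd = -6,
                                 wall_radii_mm = c(20, 32),
                                 edema_geom = list(theta = c(0, 120),
                                                   slices = 2:5),
                                 infarct_geom = list(theta = c(15, 105),
                                                     slices = 2:5),
                                 mvo_geom = list(theta = c(40, 80),
                                                 slices = 3:4,
                                                 radii = c(24, 28)),
                                 remote_geom = list(theta = c(180, 300),
                                                    slices = 1:6),
                                 noise_sd = remote_sd, background = 50,
                                 subject_id = "S01", seed = NULL) {
  qts_check(length(dim) == 3 && all(dim[1:2] >= 8) && dim[3] >= 1,
            "invalid_parameter",
            "`dim` must be c(rows, cols, slices) with rows, cols >= 8")
  qts_check(all(spacing_mm > 0), "invalid_parameter",
            "`spacing_mm` must be positive")
  check_number(remote_sd, "remote_sd", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(edema_offset_sd, "edema_offset_sd", lower = 2,
               strict_lower = TRUE)
  if (!is.null(infarct_geom))
    check_number(infarct_offset_sd, "infarct_offset_sd", lower = 5,
                 strict_lower = TRUE)
  if (!is.null(mvo_geom))
    check_number(mvo_offset_sd, "mvo_offset_sd", upper = 0)

  seed <- check_seed(seed)
  if (!is.null(seed)) set.seed(seed)

  geom_mask <- function(g) {
    if (is.null(g)) return(array(FALSE, dim))
    radii <- if (is.null(g$radii)) wall_radii_mm else g$radii
    sector_mask(dim, spacing_mm, radii, g$theta, g$slices)
  }
  myo <- sector_mask(dim, spacing_mm, wall_radii_mm, c(0, 360),
                     seq_len(dim[3]))
  edema <- geom_mask(edema_geom) & myo
  infarct <- geom_mask(infarct_geom) & myo
  mvo <- geom_mask(mvo_geom) & myo
  remote <- geom_mask(remote_geom) & myo

  qts_check(!any(infarct & !edema), "invalid_parameter",
            "infarct ground-truth mask must nest inside the edema mask")
  qts_check(!any(mvo & !infarct), "invalid_parameter",
            "MVO ground-truth mask must nest inside the infarct mask")
  qts_check(!any(remote & edema), "invalid_parameter",
            "remote ROI overlaps the edema sector")

  t2w <- array(background, dim)
  t2w[myo] <- remote_mean
  t2w[edema] <- remote_mean + edema_offset_sd * remote_sd
  lge <- array(background, dim)
  lge[myo] <- remote_mean
  lge[infarct] <- remote_mean + infarct_offset_sd * remote_sd
  lge[mvo] <- remote_mean + mvo_offset_sd * remote_sd
  if (noise_sd > 0) {
    t2w <- t2w + array(rnorm(prod(dim), 0, noise_sd), dim)
    lge <- lge + array(rnorm(prod(dim), 0, noise_sd), dim)
  }

  structure(list(subject_id = subject_id, t2w = t2w, lge = lge,
                 spacing_mm = spacing_mm, myo_mask = myo,
                 remote_mask = remote,
                 truth = list(edema = edema, infarct = infarct, mvo = mvo,
                              remote_mean = remote_mean,
                              remote_sd = remote_sd, noise_sd = noise_sd,
                              offsets_sd = c(edema = edema_offset_sd,
                                             infarct = infarct_offset_sd,
                                             mvo = mvo_offset_sd))),
            class = "cmr_study")
}

#' @export
print.cmr_study <- function(x, ...) {
  d <- dim(x$t2w)
  cat(sprintf("<cmr_study> subject %s: %dx%dx%d voxels @ %s mm\n",
              x$subject_id, d[1], d[2], d[3],
              paste(x$spacing_mm, collapse = "x")))
  cat(sprintf("  myocardium %d vox, edema %d, infarct %d, MVO %d\n",
              sum(x$myo_mask), sum(x$truth$edema), sum(x$truth$infarct),
              sum(x$truth$mvo)))
  invisible(x)
}
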