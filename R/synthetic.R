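#' Parameters of the synthetic longitudinal nodule simulator
#'
#' The simulator emulates the structure of a longitudinal CT screening
#' cohort: each patient has 3-5 visits at irregular intervals, one nodule
#' rendered as an isotropic Gaussian-profile bright blob (peak intensity
#' 1.0 before noise) at a fixed random position on a zero-mean Gaussian
#' noise background. Benign nodules keep a constant diameter; malignant
#' nodules grow linearly in calendar time, `d(t) = d0 + r * t_days / 30`,
#' so that the elapsed time between visits is genuinely informative: the
#' same total growth means something different after 2 months than after
#' 12. Baseline diameters are jittered across patients so that absolute
#' size alone does not separate the classes.
#'
#' @param n_patients number of patients.
#' @param visits_range integer `(min, max)` visits per patient, both >= 2.
#' @param interval_days `(low, high)` bounds of the uniform visit-gap draw,
#'   in days.
#' @param base_diameter_vox mean baseline nodule diameter (FWHM), voxels.
#' @param base_jitter_vox half-width of the uniform baseline-diameter
#'   jitter across patients.
#' @param growth_rate_vox_per_month linear growth rate of malignant
#'   nodules, voxels per 30 days.
#' @param noise_sd standard deviation of the additive Gaussian background
#'   noise (intensity units; blob peak is 1).
#' @param malignant_fraction fraction of patients with a malignant nodule.
#' @param volume_shape `(rows, cols, slices)` of each CT volume.
#' @param slice_spacing_mm z spacing recorded in the simulated series.
#' @param regular_intervals if `TRUE`, every gap equals the midpoint of
#'   `interval_days` (the control condition in which visit timing carries
#'   no information).
#' @param start_date first visit date.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_patients = 200L, visits_range = c(3L, 5L),
                       interval_days = c(30, 180),
                       base_diameter_vox = 6, base_jitter_vox = 2,
                       growth_rate_vox_per_month = 0.3, noise_sd = 0.1,
                       malignant_fraction = 0.5,
                       volume_shape = c(48L, 48L, 18L),
                       slice_spacing_mm = 1,
                       regular_intervals = FALSE,
                       start_date = as.Date("2015-01-01")) {
  if (n_patients < 1) stop("n_patients must be positive")
  if (visits_range[1] < 2 || visits_range[2] < visits_range[1]) {
    stop("visits_range must be ordered and >= 2")
  }
  if (interval_days[1] <= 0 || interval_days[2] < interval_days[1]) {
    stop("interval_days must be ordered and positive")
  }
  if (base_diameter_vox <= 0) stop("base_diameter_vox must be positive")
  if (base_diameter_vox >= min(volume_shape) / 2) {
    stop("base_diameter_vox must be below half the smallest volume side")
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (malignant_fraction <= 0 || malignant_fraction >= 1) {
    stop("malignant_fraction must be in (0, 1)")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      visits_range = as.integer(visits_range),
      interval_days = as.numeric(interval_days),
      base_diameter_vox = base_diameter_vox,
      base_jitter_vox = base_jitter_vox,
      growth_rate_vox_per_month = growth_rate_vox_per_month,
      noise_sd = noise_sd,
      malignant_fraction = malignant_fraction,
      volume_shape = as.integer(volume_shape),
      slice_spacing_mm = slice_spacing_mm,
      regular_intervals = isTRUE(regular_intervals),
      start_date = as.Date(start_date)
    ),
    class = "sim_params"
  )
}

# Render one Gaussian-profile blob (FWHM = diameter) into a noise volume.
render_blob <- function(shape, center, diameter, noise_sd) {
  vol <- if (noise_sd > 0) {
    array(rnorm(prod(shape), sd = noise_sd), dim = shape)
  } else {
    array(0, dim = shape)
  }
  R <- ceiling(1.5 * diameter)
  rr <- max(1L, center[1] - R):min(shape[1], center[1] + R)
  cc <- max(1L, center[2] - R):min(shape[2], center[2] + R)
  zz <- max(1L, center[3] - R):min(shape[3], center[3] + R)
  k <- 4 * log(2) / diameter^2
  gr <- exp(-k * (rr - center[1])^2)
  gc <- exp(-k * (cc - center[2])^2)
  gz <- exp(-k * (zz - center[3])^2)
  blob <- outer(outer(gr, gc), gz)
  vol[rr, cc, zz] <- vol[rr, cc, zz] + blob
  vol
}

#' Simulate one longitudinal patient
#'
#' Draws the visit schedule, baseline diameter and nodule position, then
#' renders one noisy volume per visit. Uses the current RNG stream unless
#' `seed` is given.
#'
#' @param params a [sim_params()] object.
#' @param label 0 (benign, static diameter) or 1 (malignant, growing).
#' @param patient_id identifier string.
#' @param seed optional seed for a self-contained deterministic draw.
#' @return A `sim_patient` list with `series` (list of [ct_series()]),
#'   `annotations` (list of [nodule_annotation()]), `label`, `diameters`,
#'   `gap_days` and `visit_dates`.
#' @export
simulate_patient <- function(params, label, patient_id = "P1", seed = NULL) {
  pick <- function(v) v[sample.int(length(v), 1L)]  # safe for length-1 v
  draw <- function() {
    n_visits <- pick(params$visits_range[1]:params$visits_range[2])
    gaps <- if (params$regular_intervals) {
      rep(round(mean(params$interval_days)), n_visits - 1L)
    } else {
      pmax(1, round(runif(n_visits - 1L, params$interval_days[1],
                          params$interval_days[2])))
    }
    t_days <- c(0, cumsum(gaps))
    d0 <- params$base_diameter_vox +
      runif(1, -params$base_jitter_vox, params$base_jitter_vox)
    d0 <- max(d0, 1.5)
    diam <- d0 + (label == 1) * params$growth_rate_vox_per_month * t_days / 30
    shape <- params$volume_shape
    d_final <- diam[length(diam)]
    m_ip <- ceiling(d_final)           # in-plane margin: bbox must fit
    m_z <- ceiling(d_final / 2)        # axial margin: blob core must fit
    if (2 * m_ip + 1 > min(shape[1:2]) || 2 * m_z + 1 > shape[3]) {
      stop("nodule at final visit does not fit in the volume; ",
           "increase volume_shape or reduce growth/follow-up")
    }
    center <- c(
      pick(seq(m_ip + 1L, shape[1] - m_ip)),
      pick(seq(m_ip + 1L, shape[2] - m_ip)),
      pick(seq(m_z + 1L, shape[3] - m_z))
    )
    dates <- params$start_date + t_days
    series <- vector("list", n_visits)
    anns <- vector("list", n_visits)
    for (v in seq_len(n_visits)) {
      vol <- render_blob(shape, center, diam[v], params$noise_sd)
      series[[v]] <- ct_series(vol, params$slice_spacing_mm,
                               visit_date = dates[v],
                               patient_id = patient_id)
      m <- max(1L, round(diam[v]))
      anns[[v]] <- nodule_annotation(
        center_slice_index = center[3] - 1L,
        bbox_top_left = c(center[1] - 1L - m, center[2] - 1L - m),
        bbox_bottom_right = c(center[1] - 1L + m, center[2] - 1L + m),
        label = label, n_slices = shape[3]
      )
    }
    structure(
      list(
        series = series, annotations = anns, label = as.integer(label),
        diameters = diam, gap_days = gaps, visit_dates = dates,
        patient_id = patient_id
      ),
      class = "sim_patient"
    )
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a longitudinal cohort with manifest
#'
#' Generates `n_patients` patients, exactly
#' `round(malignant_fraction * n_patients)` of them malignant (positions
#' shuffled), and the visit manifest that the preprocessing module
#' consumes.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed; the cohort is a deterministic function of
#'   `(params, seed)`.
#' @return A `sim_cohort` list with `patients`, `manifest` (data frame) and
#'   `params`.
#' @export
simulate_cohort <- function(params, seed = 0L) {
  n <- params$n_patients
  n_mal <- round(params$malignant_fraction * n)
  with_seed(seed, {
    labels <- integer(n)
    labels[sample.int(n, n_mal)] <- 1L
    patients <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      pid <- sprintf("P%04d", i)
      pat <- simulate_patient(params, labels[i], patient_id = pid)
      patients[[i]] <- pat
      rows[[i]] <- data.frame(
        patient_id = pid,
        visit_date = format(pat$visit_dates, "%Y-%m-%d"),
        center_slice = vapply(pat$annotations,
                              function(a) a$center_slice_index, integer(1)),
        bbox_r0 = vapply(pat$annotations,
                         function(a) a$bbox_top_left[1], integer(1)),
        bbox_c0 = vapply(pat$annotations,
                         function(a) a$bbox_top_left[2], integer(1)),
        bbox_r1 = vapply(pat$annotations,
                         function(a) a$bbox_bottom_right[1], integer(1)),
        bbox_c1 = vapply(pat$annotations,
                         function(a) a$bbox_bottom_right[2], integer(1)),
        label = pat$label,
        stringsAsFactors = FALSE
      )
    }
    structure(
      list(
        patients = patients,
        manifest = do.call(rbind, rows),
        params = params
      ),
      class = "sim_cohort"
    )
  })
}

#' Write a simulated cohort to disk (NIfTI volumes + manifest CSV)
#'
#' One `.nii.gz` per visit plus `manifest.csv` with a `volume` column of
#' relative paths, matching the preprocessing module's external interface.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest data frame (invisibly), with the `volume` column.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (pat in cohort$patients) {
    for (v in seq_along(pat$series)) {
      fn <- sprintf("%s_visit%02d.nii.gz", pat$patient_id, v)
      img <- RNifti::asNifti(pat$series[[v]]$slices)
      RNifti::pixdim(img) <- c(pat$series[[v]]$pixel_spacing_mm,
                               pat$series[[v]]$slice_spacing_mm)
      RNifti::writeNifti(img, file.path(dir, fn))
      paths <- c(paths, fn)
    }
  }
  manifest <- cohort$manifest
  manifest$volume <- paths
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
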