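#' Construct a longitudinal CT series object
#'
#' A `ct_series` is an ordered stack of 2-D CT slices from one visit of one
#' patient, together with the physical slice spacing along z, the in-plane
#' pixel spacing, the visit date and the patient identifier.
#'
#' @param slices a 3-D numeric array `(rows, cols, n_slices)` or a list of
#'   equally shaped 2-D matrices (stacked in order).
#' @param slice_spacing_mm positive slice spacing along z, in millimetres.
#' @param pixel_spacing_mm length-2 positive in-plane spacing (row, col), mm.
#' @param visit_date the visit date (`Date` or ISO-8601 string).
#' @param patient_id patient identifier string.
#' @return An object of class `ct_series`.
#' @export
ct_series <- function(slices, slice_spacing_mm, pixel_spacing_mm = c(1, 1),
                      visit_date = as.Date("2000-01-01"),
                      patient_id = "P0") {
  if (is.list(slices)) {
    shp <- dim(slices[[1]])
    if (is.null(shp) || length(shp) != 2L) stop("slices must be 2-D matrices")
    if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1)))) {
      stop("all slices must share the same shape")
    }
    slices <- array(unlist(slices, use.names = FALSE),
                    dim = c(shp, length(slices)))
  }
  if (length(dim(slices)) != 3L) stop("slices must form a 3-D array")
  if (dim(slices)[3] < 1L) stop("series must contain at least one slice")
  stopifnot_scalar_number(slice_spacing_mm, "slice_spacing_mm")
  if (slice_spacing_mm <= 0) stop("slice_spacing_mm must be positive")
  if (any(pixel_spacing_mm <= 0)) stop("pixel_spacing_mm must be positive")
  structure(
    list(
      slices = slices,
      slice_spacing_mm = slice_spacing_mm,
      pixel_spacing_mm = as.numeric(pixel_spacing_mm),
      visit_date = as.Date(visit_date),
      patient_id = as.character(patient_id)
    ),
    class = "ct_series"
  )
}

#' @export
print.ct_series <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf(
    "<ct_series> patient %s, visit %s: %d slices of %dx%d, dz = %g mm\n",
    x$patient_id, format(x$visit_date), d[3], d[1], d[2], x$slice_spacing_mm
  ))
  invisible(x)
}

#' Nodule annotation for one visit
#'
#' Records the center slice index (0-based), the half-open in-plane bounding
#' box `[top_left, bottom_right)` (0-based row/col pairs) and the benign (0)
#' / malignant (1) label.
#'
#' @param center_slice_index 0-based index of the most conspicuous slice.
#' @param bbox_top_left integer `(row, col)` of the box's upper-left corner.
#' @param bbox_bottom_right integer `(row, col)` one past the lower-right
#'   corner (half-open convention).
#' @param label 0 (benign) or 1 (malignant).
#' @param n_slices optional slice count used to validate the center index.
#' @return An object of class `nodule_annotation`.
#' @export
nodule_annotation <- function(center_slice_index, bbox_top_left,
                              bbox_bottom_right, label, n_slices = NULL) {
  center_slice_index <- as.integer(center_slice_index)
  if (center_slice_index < 0L) stop("center_slice_index must be >= 0")
  if (!is.null(n_slices) && center_slice_index >= n_slices) {
    stop("center_slice_index beyond end of series")
  }
  if (!all(bbox_top_left < bbox_bottom_right)) {
    stop("bbox_top_left must be strictly above-left of bbox_bottom_right")
  }
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  structure(
    list(
      center_slice_index = center_slice_index,
      bbox_top_left = as.integer(bbox_top_left),
      bbox_bottom_right = as.integer(bbox_bottom_right),
      label = as.integer(label)
    ),
    class = "nodule_annotation"
  )
}

#' Linearly resample a CT series along z
#'
#' Interpolates the slice stack to a new slice spacing. With `n` input
#' slices at spacing `s` and target spacing `t`, the output has
#' `floor((n - 1) * s / t) + 1` slices; output slice `j` (0-based) lies at
#' physical position `j * t` and is the linear interpolation of the two
#' bracketing input slices. The first input slice is always preserved
#' exactly, and resampling to the source spacing is the identity.
#'
#' @param series a [ct_series()].
#' @param target_spacing_mm positive target slice spacing in millimetres.
#' @return A [ct_series()] at the new spacing.
#' @export
resample_z <- function(series, target_spacing_mm) {
  stopifnot(inherits(series, "ct_series"))
  stopifnot_scalar_number(target_spacing_mm, "target_spacing_mm")
  if (target_spacing_mm <= 0) stop("target_spacing_mm must be positive")
  d <- dim(series$slices)
  n <- d[3]
  if (n < 2L) stop("cannot interpolate a single-slice series")
  s <- series$slice_spacing_mm
  t <- target_spacing_mm
  n_out <- floor((n - 1) * s / t) + 1L
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (j in seq_len(n_out) - 1L) {
    pos <- j * t / s                      # position in source slice index
    lo <- floor(pos)
    frac <- pos - lo
    if (frac < 1e-9 || lo >= n - 1L) {
      out[, , j + 1L] <- series$slices[, , min(lo, n - 1L) + 1L]
    } else {
      out[, , j + 1L] <- (1 - frac) * series$slices[, , lo + 1L] +
        frac * series$slices[, , lo + 2L]
    }
  }
  series$slices <- out
  series$slice_spacing_mm <- t
  series
}

#' Window and rescale CT intensities to [0, 1]
#'
#' Clips voxel values to the window `[low, high]` and maps the window
#' affinely onto `[0, 1]`. The default lung window for Hounsfield-unit data
#' is `(-1000, 400)`.
#'
#' @param voxels numeric array.
#' @param window length-2 numeric `(low, high)`, `low < high`.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(voxels, window = c(-1000, 400)) {
  low <- window[1]
  high <- window[2]
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("window must satisfy low < high")
  }
  (pmin(pmax(voxels, low), high) - low) / (high - low)
}

#' Extract a nodule-centered multiscale 3-D patch
#'
#' Crops the 10 slices with indices `[center - 5, center + 4]` and an
#' in-plane window (30x30 or 40x40) centered on the bounding-box center,
#' then windows intensities to `[0, 1]`. Out-of-bounds slices and pixels are
#' filled by edge replication, so every annotation yields a full-size patch.
#'
#' @param series a [ct_series()].
#' @param ann a [nodule_annotation()].
#' @param scale_tag `"small30"` (30x30x10) or `"large40"` (40x40x10).
#' @param window intensity window passed to [normalize_intensity()].
#' @return A `volume_patch`: a normalized 3-D array with attribute
#'   `scale_tag`.
#' @export
extract_slab <- function(series, ann, scale_tag = c("small30", "large40"),
                         window = c(-1000, 400)) {
  stopifnot(inherits(series, "ct_series"), inherits(ann, "nodule_annotation"))
  scale_tag <- match.arg(scale_tag)
  in_plane <- if (scale_tag == "small30") 30L else 40L
  d <- dim(series$slices)
  n <- d[3]
  k <- ann$center_slice_index
  z_idx <- pmin(pmax((k - 5L):(k + 4L), 0L), n - 1L) + 1L

  cr <- (ann$bbox_top_left[1] + ann$bbox_bottom_right[1]) %/% 2L
  cc <- (ann$bbox_top_left[2] + ann$bbox_bottom_right[2]) %/% 2L
  half <- in_plane %/% 2L
  r_idx <- pmin(pmax((cr - half):(cr + half - 1L), 0L), d[1] - 1L) + 1L
  c_idx <- pmin(pmax((cc - half):(cc + half - 1L), 0L), d[2] - 1L) + 1L

  vox <- normalize_intensity(series$slices[r_idx, c_idx, z_idx, drop = FALSE],
                             window)
  structure(vox, scale_tag = scale_tag, class = c("volume_patch", "array"))
}

#' Build the ordered visit sequence for one patient
#'
#' Sorts one patient's visits by date, computes the time lapse `delta_days`
#' between consecutive visits (0 for the first visit) and extracts both the
#' small (30x30x10) and large (40x40x10) patch for every visit.
#'
#' @param rows a data frame of manifest rows for a single patient, with
#'   columns `patient_id, visit_date, center_slice, bbox_r0, bbox_c0,
#'   bbox_r1, bbox_c1, label` (dates ISO-8601).
#' @param series list of [ct_series()], parallel to `rows`.
#' @param window intensity window for [normalize_intensity()].
#' @return A list of class `visit_sequence`; each element holds `small30`,
#'   `large40`, `label`, `delta_days` and `visit_date`.
#' @export
build_visit_sequence <- function(rows, series, window = c(-1000, 400)) {
  if (nrow(rows) < 1L) stop("at least one visit is required")
  if (length(series) != nrow(rows)) stop("series must be parallel to rows")
  if (length(unique(rows$patient_id)) != 1L) {
    stop("rows must belong to a single patient")
  }
  dates <- as.Date(rows$visit_date)
  if (anyDuplicated(dates)) stop("duplicate visit dates for one patient")
  ord <- order(dates)
  rows <- rows[ord, , drop = FALSE]
  series <- series[ord]
  dates <- dates[ord]
  deltas <- c(0, as.numeric(diff(dates)))

  visits <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    ann <- nodule_annotation(
      rows$center_slice[i],
      c(rows$bbox_r0[i], rows$bbox_c0[i]),
      c(rows$bbox_r1[i], rows$bbox_c1[i]),
      rows$label[i]
    )
    visits[[i]] <- list(
      small30 = extract_slab(series[[i]], ann, "small30", window),
      large40 = extract_slab(series[[i]], ann, "large40", window),
      label = ann$label,
      delta_days = deltas[i],
      visit_date = dates[i]
    )
  }
  structure(visits,
    class = "visit_sequence",
    patient_id = rows$patient_id[1],
    label = rows$label[1]
  )
}

#' Read a visit manifest CSV
#'
#' The manifest has one row per visit with columns
#' `patient_id,visit_date,center_slice,bbox_r0,bbox_c0,bbox_r1,bbox_c1,label`
#' and optionally `volume`, a path to the visit's NIfTI file.
#'
#' @param path CSV file path.
#' @return A data frame with `visit_date` parsed as `Date`.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "visit_date", "center_slice",
            "bbox_r0", "bbox_c0", "bbox_r1", "bbox_c1", "label")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "))
  m$visit_date <- as.Date(m$visit_date)
  m
}

#' Load a CT series from a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` volume and wraps it as a [ct_series()]; the
#' slice spacing is taken from the NIfTI pixdim unless overridden.
#'
#' @param path NIfTI file path.
#' @param visit_date,patient_id passed to [ct_series()].
#' @param slice_spacing_mm optional override of the header z spacing.
#' @return A [ct_series()].
#' @export
read_nifti_series <- function(path, visit_date = as.Date("2000-01-01"),
                              patient_id = "P0", slice_spacing_mm = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  vol <- array(as.numeric(img), dim = dim(img))
  ct_series(
    slices = vol,
    slice_spacing_mm = if (is.null(slice_spacing_mm)) pd[3] else
      slice_spacing_mm,
    pixel_spacing_mm = pd[1:2],
    visit_date = visit_date,
    patient_id = patient_id
  )
}
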