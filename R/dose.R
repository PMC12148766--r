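# Dose-function metrics over functional contours.

contour_voxels <- function(contour) {
  stopifnot(inherits(contour, "function_contour"))
  which(contour$values)
}

#' Functional mean lung dose
#'
#' Arithmetic (unweighted) mean dose over the voxels of a functional
#' contour.
#'
#' @param dose a `dose_grid` (see [make_dose()]) on the same grid.
#' @param contour a [threshold_contour()] result.
#' @return fMLD in Gy.
#' @export
fmld <- function(dose, contour) {
  idx <- contour_voxels(contour)
  if (!length(idx)) stop_("empty functional contour: fMLD undefined")
  if (!identical(dim(dose$values), contour$dim)) stop_("dose and contour grids differ")
  mean(dose$values[idx])
}

#' Functional V20
#'
#' Percentage of the functional contour receiving at least `threshold_gy`
#' (inclusive, default 20 Gy).
#'
#' @inheritParams fmld
#' @param threshold_gy dose threshold in Gy.
#' @return fV20 in percent of the contour volume.
#' @export
fv20 <- function(dose, contour, threshold_gy = 20) {
  idx <- contour_voxels(contour)
  if (!length(idx)) stop_("empty functional contour: fV20 undefined")
  if (!identical(dim(dose$values), contour$dim)) stop_("dose and contour grids differ")
  100 * sum(dose$values[idx] >= threshold_gy) / length(idx)
}

#' Per-patient dose-function metric table
#'
#' One record per (method, percentile level, metric). With the default four
#' methods, three levels and two metrics this is the full 24-entry table.
#' Methods whose contour is empty at a level yield an `NA` value flagged in
#' the `note` column; the pipeline continues.
#'
#' @param images named list of [function_image()]s (one per method).
#' @param dose a `dose_grid` on the same (exhale) grid, already resampled if
#'   the plan grid differed.
#' @param levels percentile thresholds (default 25, 50, 75).
#' @param patient patient label.
#' @return data.frame with columns `patient`, `method`, `level`, `metric`,
#'   `value`, `note`.
#' @export
dose_function_table <- function(images, dose, levels = c(25, 50, 75),
                                patient = 1L) {
  stopifnot(length(images) >= 1L, !is.null(names(images)))
  pct <- lapply(images, to_percentile)
  rows <- list()
  for (m in names(images)) for (lv in levels) {
    ctr <- threshold_contour(pct[[m]], lv, m)
    empty <- sum(ctr$values) == 0L
    for (metric in c("fMLD", "fV20")) {
      val <- if (empty) NA_real_ else
        if (metric == "fMLD") fmld(dose, ctr) else fv20(dose, ctr)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = patient, method = m, level = lv, metric = metric,
        value = val, note = if (empty) "empty contour" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Resample a dose grid to a reference grid
#'
#' Trilinear resampling of a dose distribution onto another grid (typically
#' the exhale planning grid). Out-of-support points get 0 Gy.
#'
#' @param dose a `dose_grid`.
#' @param ref an object carrying `dim`, `spacing`, `origin` (e.g. an
#'   [hu_image()]).
#' @return A `dose_grid` on the reference grid, with attribute
#'   `"resampled"` set to `TRUE` for provenance.
#' @export
resample_dose <- function(dose, ref) {
  ijk <- arrayInd(seq_len(prod(ref$dim)), ref$dim)
  w <- world_coords(ijk, ref$spacing, ref$origin)
  g <- world_to_grid(w, dose)
  vals <- sample_grid(dose$values, g[, 1L], g[, 2L], g[, 3L], fill = 0)
  out <- grid_obj(array(as.numeric(vals), ref$dim), ref$spacing, ref$origin,
                  "dose_grid")
  attr(out, "resampled") <- TRUE
  out
}
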