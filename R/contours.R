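# Percentile images, thresholded functional contours, and Dice overlap.

#' Convert a function image to a percentile image
#'
#' Each mask voxel is assigned `100 * (rank - 0.5) / n` with mid-ranks for
#' ties, so the output is invariant to any strictly increasing transform of
#' the input and a constant image maps to 50 everywhere.
#'
#' @param f a [function_image()].
#' @param mask optional logical array restricting the ranking (default: the
#'   image's own defined mask).
#' @return A `percentile_image`: values in \[0, 100\] on the mask, `NA`
#'   elsewhere.
#' @export
to_percentile <- function(f, mask = NULL) {
  stopifnot(inherits(f, "function_image"))
  m <- if (is.null(mask)) f$mask else as_mask_array(mask) & f$mask
  n <- sum(m)
  if (n == 0L) stop_("empty mask: no voxels to rank")
  r <- rank(f$values[m], ties.method = "average")
  vals <- array(NA_real_, f$dim)
  vals[m] <- 100 * (r - 0.5) / n
  structure(list(values = vals, mask = m, source_kind = f$kind,
                 spacing = f$spacing, origin = f$origin, dim = f$dim),
            class = "percentile_image")
}

#' Threshold a percentile image into a functional contour
#'
#' The contour keeps voxels at or above the percentile `level` (inclusive,
#' matching the ">= 25/50/75%" convention).
#'
#' @param p a [to_percentile()] result.
#' @param level percentile threshold in (0, 100), conventionally 25, 50 or 75.
#' @param method optional source-method label carried on the contour.
#' @return A `function_contour`: logical array plus threshold metadata.
#' @export
threshold_contour <- function(p, level, method = NA_character_) {
  stopifnot(inherits(p, "percentile_image"))
  if (!is.finite(level) || level <= 0 || level >= 100)
    stop_("level must lie in (0, 100)")
  sel <- p$mask & !is.na(p$values) & p$values >= level
  structure(list(values = sel, level = level, method = method,
                 spacing = p$spacing, origin = p$origin, dim = p$dim),
            class = "function_contour")
}

#' @exportS3Method base::print
print.function_contour <- function(x, ...) {
  cat(sprintf("<function_contour> >=%g%% (%s): %d voxels\n",
              x$level, x$method %||% "?", sum(x$values)))
  invisible(x)
}

#' Dice similarity coefficient of two contours
#'
#' `DSC = 2 |A n B| / (|A| + |B|)`. Two empty contours are defined as
#' perfectly overlapping (DSC 1, with a warning).
#'
#' @param a,b `function_contour`s (or logical arrays) on the same grid.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "function_contour")) a$values else as_mask_array(a)
  bv <- if (inherits(b, "function_contour")) b$values else as_mask_array(b)
  if (!identical(dim(av), dim(bv))) stop_("contours live on different grids")
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0L) {
    warning("both contours are empty; DSC defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(av & bv) / (na + nb)
}

#' Dice table of novel methods against a reference method
#'
#' Converts every function image to percentiles, thresholds at each level,
#' and reports the DSC of each non-reference method against the reference.
#'
#' @param images named list of [function_image()]s.
#' @param reference name of the reference method (default `"hu"`).
#' @param levels percentile thresholds.
#' @param patient patient label carried into the table.
#' @return data.frame with columns `patient`, `method`, `reference`,
#'   `level`, `dsc`.
#' @export
dice_table <- function(images, reference = "hu", levels = c(25, 50, 75),
                       patient = 1L) {
  stopifnot(reference %in% names(images))
  pct <- lapply(images, to_percentile)
  out <- list()
  for (m in setdiff(names(images), reference)) for (lv in levels) {
    d <- dice(threshold_contour(pct[[m]], lv, m),
              threshold_contour(pct[[reference]], lv, reference))
    out[[length(out) + 1L]] <- data.frame(patient = patient, method = m,
                                          reference = reference, level = lv,
                                          dsc = d)
  }
  do.call(rbind, out)
}
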