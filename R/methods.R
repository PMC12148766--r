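# The four voxelwise lung-function images.

#' Hounsfield-unit density-change ventilation
#'
#' Classical voxelwise ventilation. With `H_ex` the exhale HU and `H_in` the
#' inhale HU pulled to the exhale grid through the displacement field, the
#' two-material model (water at HU 0, air at HU -1000, tissue volume
#' conserved) gives the specific air-volume change
#' \deqn{SV(x) = 1000 (H_{in} - H_{ex}) / (H_{ex} (1000 + H_{in})).}
#' Voxels with `H_ex >= -10` (no measurable air) or pulled `H_in <= -990`
#' (almost pure air) are numerically unstable and are excluded from the
#' output mask; their count is reported in the `"excluded"` attribute.
#'
#' @param hu_ex,hu_in exhale and inhale [hu_image()]s.
#' @param field a [disp_field()] on the exhale grid.
#' @param mask a [lung_mask()] on the exhale grid.
#' @param max_excluded_frac abort if more than this fraction of mask voxels
#'   is excluded (signals a mask/image mismatch).
#' @return A [function_image()] of kind `"specific-volume-change"`.
#' @export
vent_hu <- function(hu_ex, hu_in, field, mask, max_excluded_frac = 0.2) {
  stopifnot(inherits(hu_ex, "hu_image"), inherits(hu_in, "hu_image"))
  m <- as_mask_array(mask)
  pulled <- pull_values(field, hu_in, interp = "trilinear")
  h_ex <- hu_ex$values
  h_in <- pulled$values
  bad <- m & (is.na(h_in) | h_ex >= -10 | h_in <= -990)
  n_bad <- sum(bad)
  if (n_bad > max_excluded_frac * sum(m))
    stop_("%d of %d mask voxels (%.0f%%) excluded by HU guards: image/mask mismatch",
          n_bad, sum(m), 100 * n_bad / sum(m))
  keep <- m & !bad
  sv <- array(NA_real_, dim(h_ex))
  sv[keep] <- 1000 * (h_in[keep] - h_ex[keep]) /
    (h_ex[keep] * (1000 + h_in[keep]))
  out <- function_image(sv, keep, "specific-volume-change",
                        hu_ex$spacing, hu_ex$origin)
  attr(out, "excluded") <- n_bad
  out
}

#' Integrated-Jacobian ventilation
#'
#' Estimates each subregion's volume-change factor as the hit-or-miss
#' sampled deformed volume divided by the region's exhale volume, then
#' recovers a voxelwise Jacobian image by [reconstruct_voxelwise()] with a
#' global equality constraint tying the reconstructed total volume to the
#' inhale lung-mask volume.
#'
#' @inheritParams vent_hu
#' @param mask_ex,mask_in exhale- and inhale-grid [lung_mask()]s; the inhale
#'   mask supplies the global deformed-volume constraint.
#' @param partition a [build_partition()] result (default: window 8, stride
#'   4 over `mask_ex`).
#' @param tau hit-or-miss relative standard-error tolerance.
#' @param seed integer seed for the sampling.
#' @param cfg a [reconstruction_config()].
#' @return A [function_image()] of kind `"jacobian"`; attributes
#'   `"diagnostics"` (solver) and `"estimates"` (regional table).
#' @export
vent_ijf <- function(hu_ex, hu_in, field, mask_ex, mask_in,
                     partition = NULL, tau = 0.01, seed = NULL,
                     cfg = reconstruction_config()) {
  partition <- partition %||% build_partition(mask_ex, tau = tau)
  vv <- prod(field$spacing)
  est <- with_seed(seed, {
    rows <- lapply(partition$regions, function(reg) {
      e <- hit_or_miss_volume(field, reg, tau = tau, seed = NULL)
      rv <- length(reg) * vv
      data.frame(value = e$value / rv, se = e$se / rv, n_samples = e$n_samples)
    })
    do.call(rbind, rows)
  })
  global_value <- sum(as_mask_array(mask_in)) * prod(mask_in$spacing)
  out <- reconstruct_voxelwise(est, partition, mask_ex, cfg = cfg,
                               global_value = global_value, kind = "jacobian")
  attr(out, "estimates") <- est
  out
}

#' Mass-conserving volume-change ventilation
#'
#' Subregional Jacobian estimates from exhale/inhale density ratios
#' ([mcvc_regional_jacobian()]), recovered voxelwise by
#' [reconstruct_voxelwise()] under the inequality bound `J >= lower_bound`
#' (no global equality).
#'
#' @inheritParams vent_ijf
#' @param mask analysis [lung_mask()] on the exhale grid.
#' @param density_floor guard on the mean mapped inhale density.
#' @return A [function_image()] of kind `"jacobian"`.
#' @export
vent_mcvc <- function(hu_ex, hu_in, field, mask, partition = NULL,
                      cfg = reconstruction_config(), density_floor = 0.01) {
  partition <- partition %||% build_partition(mask)
  rho_ex <- hu_to_density(hu_ex)
  rho_in <- hu_to_density(hu_in)
  rows <- lapply(partition$regions, function(reg)
    mcvc_regional_jacobian(rho_ex, rho_in, field, reg, density_floor))
  est <- do.call(rbind, rows)
  out <- reconstruct_voxelwise(est, partition, mask, cfg = cfg,
                               global_value = NULL, kind = "jacobian")
  attr(out, "estimates") <- est
  out
}

#' 4DCT perfusion surrogate (mass-change magnitude)
#'
#' Computes subregional mean-magnitude mass changes
#' ([perf_regional_masschange()]) using a Jacobian image (by default the
#' [vent_mcvc()] reconstruction), then recovers a voxelwise non-negative
#' mass-change-magnitude image by [reconstruct_voxelwise()] with lower
#' bound 0 and no global equality.
#'
#' @inheritParams vent_mcvc
#' @param jacobian optional precomputed [function_image()] of kind
#'   `"jacobian"`; computed via [vent_mcvc()] when `NULL`.
#' @return A [function_image()] of kind `"mass-change-magnitude"`.
#' @export
perf_image <- function(hu_ex, hu_in, field, mask, partition = NULL,
                       cfg = reconstruction_config(), jacobian = NULL) {
  partition <- partition %||% build_partition(mask)
  if (is.null(jacobian))
    jacobian <- vent_mcvc(hu_ex, hu_in, field, mask, partition, cfg)
  rho_ex <- hu_to_density(hu_ex)
  rho_in <- hu_to_density(hu_in)
  rows <- lapply(partition$regions, function(reg)
    perf_regional_masschange(rho_ex, rho_in, field, jacobian, reg))
  est <- do.call(rbind, rows)
  cfg_perf <- cfg
  cfg_perf$lower_bound <- 0
  out <- reconstruct_voxelwise(est, partition, mask, cfg = cfg_perf,
                               global_value = NULL,
                               kind = "mass-change-magnitude")
  attr(out, "estimates") <- est
  attr(out, "jacobian") <- jacobian
  out
}
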