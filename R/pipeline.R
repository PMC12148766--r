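#' Pipeline run configuration
#'
#' Bundles everything [run_comparison()] needs: phantom specifications (one
#' per synthetic patient), the set of enabled methods, partition and
#' reconstruction parameters, percentile levels, dose settings, reader
#' simulation rates, and the master seed. One seed fixes every stochastic
#' stage (phantom noise, hit-or-miss sampling, reader calls).
#'
#' @param patients list of phantom specifications, each a list of arguments
#'   for [make_phantom()] (e.g. `list(shape = 32)`).
#' @param methods subset of `c("hu", "ijf", "mcvc", "perf")`.
#' @param window,stride,tau partition parameters (see [build_partition()]).
#' @param recon a [reconstruction_config()].
#' @param levels percentile thresholds in (0, 100).
#' @param prescription_gy,target_radius_mm,falloff_mm synthetic-plan dose
#'   parameters (see [make_dose()]).
#' @param reader_rates list with `sensitivity`, `specificity`,
#'   `location_error_rate` for the simulated readers.
#' @param seed master integer seed.
#' @param output_dir directory for NIfTI/CSV/JSON outputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(patients = list(list(shape = 32)),
                       methods = c("hu", "ijf", "mcvc", "perf"),
                       window = 8L, stride = 4L, tau = 0.01,
                       recon = reconstruction_config(),
                       levels = c(25, 50, 75),
                       prescription_gy = 60, target_radius_mm = 12,
                       falloff_mm = 15,
                       reader_rates = list(sensitivity = 0.9,
                                           specificity = 0.9,
                                           location_error_rate = 0.1),
                       seed = 1L, output_dir = tempfile("vent4d_run_")) {
  if (!length(methods)) stop_("at least one method must be enabled")
  methods <- match.arg(methods, c("hu", "ijf", "mcvc", "perf"), several.ok = TRUE)
  if (any(levels <= 0 | levels >= 100)) stop_("levels must lie in (0, 100)")
  structure(list(patients = patients, methods = methods, window = window,
                 stride = stride, tau = tau, recon = recon, levels = levels,
                 prescription_gy = prescription_gy,
                 target_radius_mm = target_radius_mm, falloff_mm = falloff_mm,
                 reader_rates = reader_rates, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full phantom-to-statistics comparison pipeline
#'
#' For each (synthetic) patient: generates the phantom, computes the enabled
#' function images, converts them to percentile images and thresholded
#' contours, computes the Dice table of every novel method against the HU
#' reference, evaluates the dose-function table on a synthetic conformal
#' plan, and simulates reader calls compared by [binary_agreement()]. With
#' five or more patients, dose-function metrics are additionally tested with
#' [friedman_test()] and [posthoc_wilcoxon()]. All volumes are written as
#' NIfTI, tables as CSV, and a JSON manifest records the seed, parameters,
#' and every output file. Per-patient stage failures are recorded and the
#' pipeline continues.
#'
#' @param cfg a [run_config()].
#' @return list with `dose_function` and `dsc` tables, `agreement`
#'   summaries, `stats` (or `NULL`), `failures`, and the `manifest`.
#' @export
run_comparison <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add_file <- function(p) { files[[length(files) + 1L]] <<- p; p }
  log_lines <- character(0)
  logit <- function(fmt, ...) log_lines[[length(log_lines) + 1L]] <<- sprintf(fmt, ...)

  dft_all <- list(); dsc_all <- list(); failures <- list()
  agreement <- list(); reader_truth <- logical(0)
  for (pi in seq_along(cfg$patients)) {
    pseed <- cfg$seed + 1000L * pi
    res <- tryCatch({
      spec <- cfg$patients[[pi]]
      spec$seed <- spec$seed %||% pseed
      ph <- do.call(make_phantom, spec)
      part <- build_partition(ph$mask, cfg$window, cfg$stride, cfg$tau)
      imgs <- list()
      if ("hu" %in% cfg$methods)
        imgs$hu <- vent_hu(ph$exhale, ph$inhale, ph$field, ph$mask)
      if ("ijf" %in% cfg$methods)
        imgs$ijf <- vent_ijf(ph$exhale, ph$inhale, ph$field, ph$mask,
                             ph$mask_in, part, cfg$tau, seed = pseed + 1L,
                             cfg = cfg$recon)
      if ("mcvc" %in% cfg$methods)
        imgs$mcvc <- vent_mcvc(ph$exhale, ph$inhale, ph$field, ph$mask,
                               part, cfg$recon)
      if ("perf" %in% cfg$methods)
        imgs$perf <- perf_image(ph$exhale, ph$inhale, ph$field, ph$mask,
                                part, cfg$recon,
                                jacobian = imgs$mcvc)
      pdir <- file.path(cfg$output_dir, sprintf("patient_%02d", pi))
      dir.create(pdir, showWarnings = FALSE)
      add_file(write_volume(ph$exhale, file.path(pdir, "exhale.nii.gz")))
      add_file(write_volume(ph$inhale, file.path(pdir, "inhale.nii.gz")))
      add_file(write_volume(ph$field, file.path(pdir, "field.nii.gz")))
      add_file(write_volume(ph$mask, file.path(pdir, "mask.nii.gz")))
      for (m in names(imgs))
        add_file(write_volume(imgs[[m]], file.path(pdir, sprintf("func_%s.nii.gz", m))))
      pcts <- lapply(imgs, to_percentile)
      for (m in names(imgs)) for (lv in cfg$levels) {
        ctr <- threshold_contour(pcts[[m]], lv, m)
        add_file(write_volume(ctr, file.path(pdir, sprintf("contour_%s_%d.nii.gz", m, lv))))
      }
      # dose on the exhale grid, centered near the lung with an offset target
      tgt <- ph$lung_center + c(0.4, 0, 0) * ph$lung_semiaxes
      dose <- make_dose(ph$exhale$dim, ph$exhale$spacing, ph$exhale$origin,
                        target_center = tgt,
                        target_radius = cfg$target_radius_mm,
                        prescription_gy = cfg$prescription_gy,
                        falloff_mm = cfg$falloff_mm)
      add_file(write_volume(dose, file.path(pdir, "dose.nii.gz")))
      dft <- dose_function_table(imgs, dose, cfg$levels, patient = pi)
      dsc <- if ("hu" %in% names(imgs) && length(imgs) > 1L)
        dice_table(imgs, reference = "hu", levels = cfg$levels, patient = pi)
      else {
        logit("patient %d: DSC stage skipped (no comparator against the HU reference)", pi)
        NULL
      }
      list(dft = dft, dsc = dsc,
           truth_defect = any(ph$truth$defect_mask))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(patient = pi,
                                                message = conditionMessage(res))
      logit("patient %d FAILED: %s", pi, conditionMessage(res))
      next
    }
    dft_all[[length(dft_all) + 1L]] <- res$dft
    if (!is.null(res$dsc)) dsc_all[[length(dsc_all) + 1L]] <- res$dsc
    reader_truth <- c(reader_truth, res$truth_defect)
  }

  dft <- if (length(dft_all)) do.call(rbind, dft_all) else NULL
  dsc <- if (length(dsc_all)) do.call(rbind, dsc_all) else NULL

  # simulated reader arms: each method read once per patient, compared to HU
  if (length(reader_truth) && "hu" %in% cfg$methods && length(cfg$methods) > 1L) {
    rr <- cfg$reader_rates
    ref <- simulate_reader(reader_truth, rr$sensitivity, rr$specificity,
                           rr$location_error_rate, method = "hu",
                           seed = cfg$seed + 11L)
    for (m in setdiff(cfg$methods, "hu")) {
      tst <- simulate_reader(reader_truth, rr$sensitivity, rr$specificity,
                             rr$location_error_rate, method = m,
                             seed = cfg$seed + 11L + match(m, cfg$methods))
      agreement[[m]] <- binary_agreement(ref, tst, use_location = FALSE)
    }
  }

  stats <- NULL
  if (!is.null(dft) && length(unique(dft$patient)) >= 5L &&
      "hu" %in% cfg$methods && length(cfg$methods) > 1L) {
    stats <- list()
    for (metric in c("fMLD", "fV20")) {
      sub <- dft[dft$metric == metric & !is.na(dft$value), ]
      agg <- stats::aggregate(value ~ patient + method, sub, mean)
      wide <- stats::reshape(agg, idvar = "patient", timevar = "method",
                             direction = "wide")
      mat <- as.matrix(wide[, -1, drop = FALSE])
      colnames(mat) <- sub("^value\\.", "", colnames(mat))
      if (anyNA(mat)) next
      tests <- as.list(as.data.frame(mat[, setdiff(colnames(mat), "hu"), drop = FALSE]))
      stats[[metric]] <- list(
        friedman = friedman_test(mat),
        posthoc = posthoc_wilcoxon(mat[, "hu"], tests))
    }
  } else {
    logit("statistics stage skipped (needs >= 5 patients and the HU reference)")
  }

  write_tab <- function(tab, name) {
    p <- file.path(cfg$output_dir, name)
    utils::write.csv(tab, p, row.names = FALSE)
    add_file(p)
  }
  if (!is.null(dft)) write_tab(dft, "dose_function.csv")
  if (!is.null(dsc)) write_tab(dsc, "dsc.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("vent4d")),
    seed = cfg$seed, methods = cfg$methods,
    partition = list(window = cfg$window, stride = cfg$stride, tau = cfg$tau),
    levels = cfg$levels, n_patients = length(cfg$patients),
    n_failures = length(failures),
    files = vapply(files, identity, character(1)),
    log = log_lines)
  mp <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)

  list(dose_function = dft, dsc = dsc, agreement = agreement, stats = stats,
       failures = failures, manifest = manifest, manifest_path = mp,
       output_dir = cfg$output_dir)
}
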