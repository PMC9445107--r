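#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds away from zero), matching the
#' rounding style of printed phantom-study tables; base R's `round()`
#' rounds half to even.
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percent excess of one resolution over another
#'
#' `100 * (a - b) / b`, rounded half away from zero. Used for headline
#' comparisons such as "FWHM of nuclide A is X% worse than nuclide B".
#' @param a,b values to compare (mm); `b > 0`.
#' @param digits decimals (0 for headline comparisons, 1 for table work).
#' @return percent excess.
#' @export
percent_excess <- function(a, b, digits = 0) {
  if (b <= 0) stop("reference value must be > 0")
  round_half_away(100 * (a - b) / b, digits)
}

.check_fwhm_table <- function(fwhm_table) {
  need <- c("nuclide", "weight_setup", "contrast_label", "fwhm_mean_mm")
  if (!all(need %in% names(fwhm_table)))
    stop("fwhm table needs columns ", paste(need, collapse = ", "))
  fwhm_table$setup <- paste(fwhm_table$contrast_label,
                            fwhm_table$weight_setup)
  fwhm_table
}

#' Maximum pairwise FWHM excess across setups
#'
#' For every setup (contrast ratio x weight combination) present in the
#' table, computes [percent_excess()] of the target nuclide's FWHM over
#' the reference nuclide's, and returns the maximum (integer-rounded).
#'
#' @param fwhm_table data frame with columns `nuclide`, `weight_setup`,
#'   `contrast_label`, `fwhm_mean_mm` (see [nema_fwhm_table()]).
#' @param target,reference nuclide identifiers.
#' @return maximum percent excess across setups.
#' @export
max_pairwise_excess <- function(fwhm_table, target, reference) {
  tab <- .check_fwhm_table(fwhm_table)
  setups <- unique(tab$setup)
  pe <- vapply(setups, function(s) {
    a <- tab$fwhm_mean_mm[tab$setup == s & tab$nuclide == target]
    b <- tab$fwhm_mean_mm[tab$setup == s & tab$nuclide == reference]
    if (length(a) != 1 || length(b) != 1)
      stop("missing FWHM entry for setup '", s, "' (need both ", target,
           " and ", reference, ")")
    percent_excess(a, b, digits = 0)
  }, numeric(1))
  max(pe)
}

#' Resolution gain at the higher sphere-to-background contrast
#'
#' For every nuclide x weight cell with both contrast levels present,
#' computes `100 * (fwhm_low - fwhm_high) / fwhm_low` (how much better
#' the resolution is at high contrast) and returns the maximum,
#' integer-rounded.
#'
#' @param fwhm_table as in [max_pairwise_excess()]; `contrast_label` must
#'   contain `"4:1"` and `"8:1"`.
#' @return maximum percent gain.
#' @export
contrast_gain <- function(fwhm_table) {
  tab <- .check_fwhm_table(fwhm_table)
  cells <- unique(tab[, c("nuclide", "weight_setup")])
  gains <- vapply(seq_len(nrow(cells)), function(i) {
    sel <- tab$nuclide == cells$nuclide[i] &
      tab$weight_setup == cells$weight_setup[i]
    lo <- tab$fwhm_mean_mm[sel & tab$contrast_label == "4:1"]
    hi <- tab$fwhm_mean_mm[sel & tab$contrast_label == "8:1"]
    if (length(lo) != 1 || length(hi) != 1)
      stop("missing contrast level for ", cells$nuclide[i], " ",
           cells$weight_setup[i])
    100 * (lo - hi) / lo
  }, numeric(1))
  round_half_away(max(gains), 0)
}

#' Percent decrease in detected trues under the obese setup
#'
#' `100 * (normal - obese) / normal`, one decimal. If the obese count
#' exceeds the normal count (possible under noise) the result is negative
#' and a warning is raised instead of an error.
#' @param normal_trues,obese_trues total true counts.
#' @return percent decrease, 1 decimal.
#' @export
trues_decrease <- function(normal_trues, obese_trues) {
  if (normal_trues <= 0) stop("normal_trues must be > 0")
  if (obese_trues > normal_trues)
    warning("obese trues exceed normal trues")
  round_half_away(100 * (normal_trues - obese_trues) / normal_trues, 1)
}

#' Sphere-to-background concentration ratio, 1 decimal
#' @param sphere_conc,bg_conc concentrations (kBq/mL, > 0).
#' @return ratio rounded to 1 decimal.
#' @export
ratio_check <- function(sphere_conc, bg_conc) {
  if (sphere_conc <= 0 || bg_conc <= 0) stop("concentrations must be > 0")
  round_half_away(sphere_conc / bg_conc, 1)
}

#' Packaged phantom acquisition tables
#'
#' `nema_count_table()` returns the per-acquisition record of the
#' reference nuclide-comparison study (actual sphere and background
#' concentrations at scan start, detected trues in Mcts, acquisition
#' duration); `nema_fwhm_table()` the corresponding fitted spatial
#' resolution (mean +/- SD over the six spheres) per nuclide and setup.
#' @return a data frame.
#' @export
nema_count_table <- function() {
  utils::read.csv(system.file("extdata", "nema_counts.csv",
                              package = "nemaiq", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname nema_count_table
#' @export
nema_fwhm_table <- function() {
  utils::read.csv(system.file("extdata", "nema_fwhm.csv",
                              package = "nemaiq", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Cross-nuclide comparison statistics from the packaged tables
#'
#' Recomputes, from the packaged acquisition and resolution tables, the
#' study's headline comparison numbers: the maximum FWHM excess of 68Ga
#' over 18F and over 64Cu across setups, the maximum resolution gain at
#' the higher sphere-to-background contrast, the per-acquisition decrease
#' in detected trues under the obese setup (with its range), and the
#' measured sphere-to-background concentration ratios.
#' @return a list with elements `fwhm_excess`, `contrast_gain_pct`,
#'   `trues_decrease` (data frame), `trues_decrease_range`,
#'   `contrast_ratios` (data frame).
#' @export
replicate_tables <- function() {
  counts <- nema_count_table()
  fwhm <- nema_fwhm_table()
  td <- do.call(rbind, lapply(split(counts, list(counts$nuclide,
                                                 counts$contrast_label)),
    function(g) {
      n <- g[g$weight_setup == "normal", ]; o <- g[g$weight_setup == "obese", ]
      data.frame(nuclide = n$nuclide, contrast_label = n$contrast_label,
                 measured_ratio = n$measured_ratio,
                 decrease_pct = trues_decrease(n$trues_mcts, o$trues_mcts))
    }))
  rownames(td) <- NULL
  ratios <- data.frame(
    nuclide = counts$nuclide, weight_setup = counts$weight_setup,
    contrast_label = counts$contrast_label,
    ratio = mapply(ratio_check, counts$sphere_kbq_ml,
                   counts$background_kbq_ml))
  list(
    fwhm_excess = c(
      Ga68_vs_F18 = max_pairwise_excess(fwhm, "Ga68", "F18"),
      Ga68_vs_Cu64 = max_pairwise_excess(fwhm, "Ga68", "Cu64")),
    contrast_gain_pct = contrast_gain(fwhm),
    trues_decrease = td,
    trues_decrease_range = range(td$decrease_pct),
    contrast_ratios = ratios)
}

#' Run a full simulate-analyze-fit experiment
#'
#' Orchestrates one phantom acquisition: rasterize the NEMA body phantom
#' at the requested sphere-to-background ratio, degrade it for the given
#' nuclide and weight setup, segment the spheres, compute the image
#' quality metric suite and fit the per-sphere resolution. Fully
#' reproducible from the configuration (including the seed).
#'
#' @param nuclide nuclide identifier (see [get_nuclide()]) or `NULL` for a
#'   range-free source.
#' @param ratio sphere-to-background activity ratio (4 or 8).
#' @param weight `"normal"` or `"obese"`; obese keeps
#'   `obese_count_factor` of the trues.
#' @param trues expected total trues of the normal-weight acquisition.
#' @param seed integer noise seed.
#' @param system_fwhm system PSF FWHM, mm.
#' @param obese_count_factor trues retained under the obese setup.
#' @param shape,spacing,supersampling grid settings, see
#'   [rasterize_phantom()].
#' @param edge_enhancement optional unsharp-mask settings, see
#'   [degradation_spec()].
#' @param fit logical; fit per-sphere resolution profiles.
#' @param truth optionally, a pre-rasterized truth [grid3d()] matching
#'   `spec` (saves repeating the rasterization across nuclides).
#' @param out_dir if non-`NULL`, write `truth.nii.gz`, `degraded.nii.gz`,
#'   `spheres.csv` and `report.json` there.
#' @return an `iq_report` list: `schema_version`, `nuclide`,
#'   `contrast_label`, `weight_setup`, `per_sphere` (data frame ordered by
#'   diameter), `cov_bg`, `bg_mean`, `bg_sd`, `lung_error_pct`,
#'   `resolution` (mean/sd/n), `provenance`.
#' @export
run_experiment <- function(nuclide = "F18", ratio = 4, weight = "normal",
                           trues = 7.1e7, seed = 1L, system_fwhm = 4.4,
                           obese_count_factor = 0.62,
                           shape = c(440, 440, 97),
                           spacing = c(1.65, 1.65, 1.5),
                           supersampling = 4L, edge_enhancement = NULL,
                           fit = TRUE, truth = NULL, out_dir = NULL) {
  weight <- match.arg(weight, c("normal", "obese"))
  nuc <- if (is.null(nuclide)) NULL else get_nuclide(nuclide)
  spec <- nema_phantom(ratio = ratio)
  if (is.null(truth))
    truth <- rasterize_phantom(spec, spacing = spacing, shape = shape,
                               supersampling = supersampling)
  deg <- degradation_spec(
    system_fwhm = system_fwhm, nuclide = nuc, target_trues = trues,
    obese_count_factor = if (weight == "obese") obese_count_factor else 1,
    edge_enhancement = edge_enhancement, seed = seed)
  img <- degrade_image(truth, deg)

  bg <- place_background_vois(img, spec)
  ord <- order(spec$sphere_diameters)
  rows <- lapply(ord, function(i) {
    dia <- spec$sphere_diameters[i]
    ctr <- spec$sphere_centers[i, ]
    mask <- segment_sphere(img, ctr, bg$mean, dia)
    rc <- recovery_coefficients(img, mask, spec$sphere_activity)
    crc <- contrast_recovery(rc$measured_mean, bg$mean,
                             spec$sphere_activity, spec$background_activity)
    cnr <- if (bg$sd > 0)
      contrast_noise_ratio(rc$measured_mean, bg$mean, bg$sd) else NA_real_
    data.frame(diameter_mm = dia, n_voxels = length(mask),
               measured_mean = rc$measured_mean,
               measured_max = rc$measured_max,
               measured_peak = rc$measured_peak,
               rc_mean = rc$rc_mean, rc_max = rc$rc_max,
               rc_peak = rc$rc_peak, crc_pct = crc, cnr = cnr)
  })
  per_sphere <- do.call(rbind, rows)
  lung <- lung_count_error(img, spec, bg)

  resolution <- list(mean = NA_real_, sd = NA_real_, n = 0L)
  if (fit) {
    fits <- lapply(ord, function(i)
      fit_resolution(img, list(center = spec$sphere_centers[i, ],
                               diameter = spec$sphere_diameters[i],
                               wall = spec$wall_thickness),
                     background_mean = bg$mean))
    per_sphere$fwhm_mm <- vapply(fits, function(f) f$model$fwhm, numeric(1))
    per_sphere$fit_converged <- vapply(fits, function(f) f$converged,
                                       logical(1))
    resolution <- aggregate_resolution(fits)
  }

  report <- list(
    schema_version = "1.0",
    nuclide = if (is.null(nuclide)) "none" else nuclide,
    contrast_label = paste0(ratio, ":1"),
    weight_setup = weight,
    per_sphere = per_sphere,
    cov_bg = bg$cov_bg,
    bg_mean = bg$mean,
    bg_sd = bg$sd,
    lung_error_pct = lung,
    resolution = resolution,
    provenance = list(
      nuclide = if (is.null(nuclide)) "none" else nuclide,
      ratio = ratio, weight = weight, trues = trues, seed = seed,
      system_fwhm = system_fwhm,
      obese_count_factor = if (weight == "obese") obese_count_factor else 1,
      shape = shape, spacing = spacing, supersampling = supersampling,
      edge_enhancement = edge_enhancement))
  class(report) <- "iq_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_grid_nifti(truth, file.path(out_dir, "truth.nii.gz"))
    write_grid_nifti(img, file.path(out_dir, "degraded.nii.gz"))
    utils::write.csv(per_sphere, file.path(out_dir, "spheres.csv"),
                     row.names = FALSE)
    writeLines(report_json(report), file.path(out_dir, "report.json"))
  }
  report
}

#' Serialize an IQ report to JSON
#'
#' Deterministic serialization (fixed field order, 10 significant digits)
#' so identical configurations give byte-identical reports.
#' @param report an `iq_report` from [run_experiment()].
#' @return a JSON string.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = 10, pretty = TRUE, na = "null",
                                dataframe = "columns"))
}

#' @export
print.iq_report <- function(x, ...) {
  cat(sprintf("<iq_report> %s, %s contrast, %s setup\n", x$nuclide,
              x$contrast_label, x$weight_setup))
  cat(sprintf("  CoV_BG %.1f%%, lung error %.2f%%", 100 * x$cov_bg,
              x$lung_error_pct))
  if (is.finite(x$resolution$mean))
    cat(sprintf(", FWHM %.2f +/- %.2f mm", x$resolution$mean,
                x$resolution$sd))
  cat("\n")
  print(x$per_sphere, digits = 3)
  invisible(x)
}
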