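#' Per-electrode site measurement
#'
#' Bundle of the clinical covariates measured for one electrode: the
#' electrode-retina distance (ERD), retinal thickness and fibrotic tissue
#' thickness from OCT B-scans, electrode impedance, and the perceptual
#' threshold (current amplitude at which the participant detects a phosphene
#' half of the time). Fibrosis grows on the electrode surface, so the ERD can
#' never be smaller than the fibrotic thickness; when the array is apposed to
#' the retina the two are equal.
#'
#' @param label electrode label, e.g. `"C5"`.
#' @param erd_um electrode-retina distance, micrometers.
#' @param thickness_um retinal thickness beneath the electrode, micrometers.
#' @param fibrosis_um fibrotic tissue thickness on the electrode surface,
#'   micrometers (0 if absent).
#' @param impedance_kohm electrode impedance, kilo-ohms.
#' @param threshold_uA perceptual threshold, microamps (`NA` if not measured).
#' @param visible was the electrode visible on at least one B-scan?
#' @return A list of class `electrode_site`.
#' @export
electrode_site <- function(label, erd_um, thickness_um, fibrosis_um = 0,
                           impedance_kohm = NA_real_,
                           threshold_uA = NA_real_, visible = TRUE) {
  if (!is.finite(erd_um) || erd_um < 0) stop("erd_um must be >= 0")
  if (!is.finite(fibrosis_um) || fibrosis_um < 0)
    stop("fibrosis_um must be >= 0")
  if (erd_um < fibrosis_um)
    stop("electrode-retina distance (", erd_um,
         " um) cannot be smaller than fibrotic thickness (", fibrosis_um,
         " um)")
  if (!is.finite(thickness_um) || thickness_um <= 0)
    stop("thickness_um must be positive")
  structure(list(label = as.character(label), erd_um = erd_um,
                 thickness_um = thickness_um, fibrosis_um = fibrosis_um,
                 impedance_kohm = impedance_kohm,
                 threshold_uA = threshold_uA, visible = isTRUE(visible)),
            class = "electrode_site")
}

site_table_cols <- c("label", "erd_um", "thickness_um", "fibrosis_um",
                     "impedance_kohm", "threshold_uA", "visible")

#' Generate a synthetic patient measurement table
#'
#' Stands in for clinical OCT measurement tables, which are not publicly
#' available. Draws per-electrode geometry from the ranges observed
#' clinically (ERD spanning 10--440 um across electrodes in the most variable
#' eye, retinal thickness 100--350 um) and plants a linear dependence of the
#' perceptual threshold on ERD and thickness plus Gaussian noise, so that
#' regression analyses can be exercised against a known ground truth. With
#' `noise_sd = 0` the planted coefficients are exactly recoverable by
#' ordinary least squares.
#'
#' @param n_electrodes number of electrodes to generate (default 60).
#' @param seed integer seed; the table is reproducible for a fixed seed.
#' @param ranges named list of `c(min, max)` ranges (micrometers /
#'   kilo-ohms) for `erd`, `thickness`, `fibrosis`, `impedance`.
#' @param coef named list with the planted threshold model
#'   `threshold = intercept + b_erd * erd_um + b_thickness * thickness_um`:
#'   entries `intercept` (uA), `b_erd` (uA/um), `b_thickness` (uA/um),
#'   `noise_sd` (uA). Defaults give thresholds in the clinically observed
#'   sub-677 uA range.
#' @param p_fibrosis probability an electrode carries fibrotic tissue.
#' @param p_invisible probability an electrode is not visible on any B-scan.
#' @param array electrode array specification supplying labels.
#' @return A `data.frame` (class `site_table`) with columns
#'   `r paste(site_table_cols, collapse = ", ")`.
#' @examples
#' pat <- generate_synthetic_patient(10, seed = 1)
#' range(pat$erd_um)
#' @export
generate_synthetic_patient <- function(n_electrodes = 60L, seed,
                                       ranges = list(),
                                       coef = list(),
                                       p_fibrosis = 0.3,
                                       p_invisible = 0.05,
                                       array = electrode_array_spec()) {
  if (!is.numeric(n_electrodes) || n_electrodes < 1)
    stop("n_electrodes must be a positive count")
  n <- as.integer(n_electrodes)
  if (missing(seed)) stop("a seed is required for reproducibility")
  rng <- utils::modifyList(list(erd = c(10, 440), thickness = c(100, 350),
                                fibrosis = c(20, 80), impedance = c(10, 60)),
                           ranges)
  for (nm in names(rng))
    if (rng[[nm]][1] < 0 || diff(rng[[nm]]) < 0)
      stop("invalid range for ", nm)
  cf <- utils::modifyList(list(intercept = 200, b_erd = 0.9,
                               b_thickness = -0.5, noise_sd = 30), coef)

  with_seed(seed, {
    labels <- array$sites$label
    if (n > length(labels)) labels <- c(labels, paste0("X", seq_len(n)))
    erd <- runif(n, rng$erd[1], rng$erd[2])
    thick <- runif(n, rng$thickness[1], rng$thickness[2])
    fib <- ifelse(runif(n) < p_fibrosis,
                  pmin(runif(n, rng$fibrosis[1], rng$fibrosis[2]), erd), 0)
    imp <- runif(n, rng$impedance[1], rng$impedance[2])
    thr <- cf$intercept + cf$b_erd * erd + cf$b_thickness * thick +
      if (cf$noise_sd > 0) stats::rnorm(n, 0, cf$noise_sd) else 0
    thr <- pmax(thr, 1)
    vis <- runif(n) >= p_invisible
    out <- data.frame(label = labels[seq_len(n)], erd_um = erd,
                      thickness_um = thick, fibrosis_um = fib,
                      impedance_kohm = imp, threshold_uA = thr,
                      visible = vis, stringsAsFactors = FALSE)
    class(out) <- c("site_table", "data.frame")
    out
  })
}

#' Read / write a measurement table
#'
#' CSV interchange with the fixed header
#' `label,erd_um,thickness_um,fibrosis_um,impedance_kohm,threshold_uA,visible`.
#'
#' @param path file path.
#' @return `read_measurements` returns a validated `site_table` data frame.
#' @export
read_measurements <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(site_table_cols, names(tab))
  if (length(missing_cols))
    stop("measurement table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab <- tab[site_table_cols]
  tab$visible <- as.logical(tab$visible)
  # row-wise invariants
  for (i in seq_len(nrow(tab)))
    electrode_site(tab$label[i], tab$erd_um[i], tab$thickness_um[i],
                   tab$fibrosis_um[i], tab$impedance_kohm[i],
                   tab$threshold_uA[i], tab$visible[i])
  class(tab) <- c("site_table", "data.frame")
  tab
}

#' @rdname read_measurements
#' @param tab a `site_table` data frame.
#' @export
write_measurements <- function(tab, path) {
  stopifnot(all(site_table_cols %in% names(tab)))
  write.csv(as.data.frame(tab)[site_table_cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

# one row of a site table -> electrode_site
site_from_row <- function(tab, i) {
  electrode_site(tab$label[i], tab$erd_um[i], tab$thickness_um[i],
                 tab$fibrosis_um[i], tab$impedance_kohm[i],
                 tab$threshold_uA[i], tab$visible[i])
}
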