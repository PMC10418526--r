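#' Somas activated at a given amplitude
#'
#' A neuron counts as activated when its bisection threshold is defined and
#' does not exceed the stimulus amplitude; excluded neurons (thin retina,
#' unbuildable) never activate. Because the spike response is monotone in
#' amplitude this re-uses the stored thresholds instead of re-simulating.
#'
#' @param table a `threshold_table`.
#' @param electrode electrode label.
#' @param amplitude_uA stimulus amplitude.
#' @return integer vector of activated neuron ids.
#' @export
activated_set <- function(table, electrode, amplitude_uA) {
  sel <- table$electrode == electrode & !table$excluded &
    !is.na(table$threshold_uA) & table$threshold_uA <= amplitude_uA
  table$neuron[sel]
}

#' Convex hull area of a soma point set
#'
#' Area of the convex hull (shoelace formula over [grDevices::chull()]
#' vertices); zero for fewer than three non-collinear points.
#'
#' @param xy_um n x 2 matrix of positions in micrometers.
#' @return area in mm^2.
#' @export
hull_area <- function(xy_um) {
  xy_um <- matrix(xy_um, ncol = 2)
  if (nrow(xy_um) < 3) return(0)
  h <- grDevices::chull(xy_um)
  if (length(h) < 3) return(0)
  x <- xy_um[h, 1] * 1e-3
  y <- xy_um[h, 2] * 1e-3
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Convert retinal area to degrees of visual angle
#'
#' Uses the retinal magnification of 288 um per degree, so
#' `deg^2 = mm^2 / 0.288^2`.
#'
#' @param area_mm2 area on the retina, mm^2.
#' @param um_per_deg conversion factor (default 288).
#' @return area in deg^2.
#' @export
to_visual_degrees <- function(area_mm2, um_per_deg = 288) {
  stopifnot(all(area_mm2 >= 0))
  area_mm2 / (um_per_deg * 1e-3)^2
}

#' Phosphene-size sweep over stimulus amplitude
#'
#' Modulates the stimulus between multiples of the electrode threshold
#' (default 1.2x to 6x in 13 steps), collects the set of activated somas at
#' each multiple, fits a convex hull around the activated cell bodies,
#' converts its area to degrees of visual angle, and fits an
#' ordinary-least-squares line of area (deg^2) against the threshold
#' multiple — the modelled counterpart of phosphene size growing with
#' amplitude.
#'
#' @param table a `threshold_table` containing the electrode.
#' @param electrode electrode label.
#' @param multiples amplitude as multiples of the electrode threshold.
#' @return A `phosphene_sweep`: data frame (`multiple`, `amplitude_uA`,
#'   `n_activated`, `area_mm2`, `area_deg2`) plus `slope_deg2_per_x`,
#'   `intercept_deg2` and the electrode threshold.
#' @export
amplitude_sweep <- function(table, electrode,
                            multiples = seq(1.2, 6.0, length.out = 13)) {
  et <- electrode_threshold(table[table$electrode == electrode, ,
                                  drop = FALSE])
  if (is.na(et$min_uA))
    stop("electrode threshold undefined for ", electrode,
         ": no activated, included neuron")
  thr <- et$min_uA
  rows <- lapply(multiples, function(m) {
    ids <- activated_set(table, electrode, m * thr)
    sel <- table$electrode == electrode & table$neuron %in% ids
    a_mm2 <- hull_area(as.matrix(table[sel, c("soma_x_um", "soma_y_um")]))
    data.frame(multiple = m, amplitude_uA = m * thr,
               n_activated = length(ids), area_mm2 = a_mm2,
               area_deg2 = to_visual_degrees(a_mm2))
  })
  sweep <- do.call(rbind, rows)
  fit <- ols_fit(sweep["multiple"], sweep$area_deg2)
  structure(list(electrode = electrode, threshold_uA = thr, sweep = sweep,
                 slope_deg2_per_x = fit$coefficients$estimate[2],
                 intercept_deg2 = fit$coefficients$estimate[1],
                 fit = fit),
            class = "phosphene_sweep")
}

#' @export
print.phosphene_sweep <- function(x, ...) {
  cat(sprintf(
    "<phosphene_sweep> electrode %s (threshold %.2f uA): slope %.3f deg^2 per x-threshold\n",
    x$electrode, x$threshold_uA, x$slope_deg2_per_x))
  print(x$sweep, row.names = FALSE)
  invisible(x)
}

#' Write sweep results
#'
#' CSV of the per-multiple table and a JSON file with the fitted slope.
#'
#' @param sweep a `phosphene_sweep`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @export
write_sweep <- function(sweep, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(sweep$sweep, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(electrode = sweep$electrode,
                              threshold_uA = sweep$threshold_uA,
                              slope_deg2_per_x = sweep$slope_deg2_per_x,
                              intercept_deg2 = sweep$intercept_deg2,
                              n_points = nrow(sweep$sweep)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(sweep)
}
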