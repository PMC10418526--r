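#' Electrode array specification
#'
#' Describes a 6 x 10 grid of platinum disc electrodes (labels A1--F10,
#' rows A--F, columns 1--10) on an insulating substrate, matching the layout
#' of a 60-channel epiretinal implant.
#'
#' @param n_rows,n_cols grid dimensions (default 6 x 10).
#' @param electrode_diameter_um disc diameter in micrometers (default 200).
#' @param pitch_um center-to-center spacing in micrometers (default 525).
#' @return An object of class `electrode_array_spec` with the label grid and
#'   per-electrode x-y offsets (micrometers, array centered at the origin).
#' @examples
#' arr <- electrode_array_spec()
#' nrow(arr$sites)      # 60
#' @export
electrode_array_spec <- function(n_rows = 6L, n_cols = 10L,
                                 electrode_diameter_um = 200,
                                 pitch_um = 525) {
  stopifnot(n_rows >= 1, n_cols >= 1, electrode_diameter_um > 0,
            electrode_diameter_um < pitch_um)
  rows <- LETTERS[seq_len(n_rows)]
  sites <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  labels <- paste0(rows[sites$row], sites$col)
  # array centered on the origin; rows advance along +y, columns along +x
  x <- (sites$col - (n_cols + 1) / 2) * pitch_um
  y <- (sites$row - (n_rows + 1) / 2) * pitch_um
  stopifnot(!anyDuplicated(labels))
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    electrode_diameter_um = electrode_diameter_um,
    pitch_um = pitch_um,
    sites = data.frame(label = labels, x_um = x, y_um = y,
                       stringsAsFactors = FALSE)
  ), class = "electrode_array_spec")
}

#' @export
print.electrode_array_spec <- function(x, ...) {
  cat(sprintf("<electrode_array_spec> %d x %d sites, %g um discs at %g um pitch\n",
              x$n_rows, x$n_cols, x$electrode_diameter_um, x$pitch_um))
  invisible(x)
}

# x-y offsets of every electrode relative to a chosen active electrode
array_offsets <- function(array, active_label) {
  s <- array$sites
  i <- match(active_label, s$label)
  if (is.na(i)) stop("unknown electrode label: ", active_label)
  data.frame(label = s$label, x_um = s$x_um - s$x_um[i],
             y_um = s$y_um - s$y_um[i], stringsAsFactors = FALSE)
}
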