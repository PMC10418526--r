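#' Threshold search bracket configuration
#'
#' @param initial_guess_uA first amplitude probed (default 10).
#' @param cap_uA upper search limit; a neuron that does not spike at the cap
#'   receives the not-activated sentinel `NA` (default 10000).
#' @param tol_uA bisection convergence (default 0.1).
#' @return list of class `bracket_config`.
#' @export
bracket_config <- function(initial_guess_uA = 10, cap_uA = 10000,
                           tol_uA = 0.1) {
  stopifnot(initial_guess_uA > 0, cap_uA > initial_guess_uA, tol_uA > 0)
  structure(list(initial_guess_uA = initial_guess_uA, cap_uA = cap_uA,
                 tol_uA = tol_uA), class = "bracket_config")
}

#' Bisection threshold on a monotone spike response
#'
#' Core search used for every neuron: the upper bracket is found by doubling
#' from the initial guess until a spike occurs (or the cap is reached), then
#' the bracket is halved until it is narrower than `tol_uA`. The returned
#' value is the upper bound of the final bracket, so for a monotone response
#' it lies within `tol_uA` above the true threshold. Deterministic.
#'
#' @param spike_fun `function(amplitude_uA) -> logical`.
#' @param bracket a [bracket_config()].
#' @return threshold in uA, or `NA_real_` if no spike occurs at the cap.
#' @export
bisect_threshold <- function(spike_fun, bracket = bracket_config()) {
  lo <- 0
  hi <- bracket$initial_guess_uA
  while (!isTRUE(spike_fun(hi))) {
    lo <- hi
    hi <- hi * 2
    if (hi > bracket$cap_uA) {
      if (lo >= bracket$cap_uA || !isTRUE(spike_fun(bracket$cap_uA)))
        return(NA_real_)
      hi <- bracket$cap_uA
      break
    }
  }
  while (hi - lo > bracket$tol_uA) {
    mid <- (lo + hi) / 2
    if (isTRUE(spike_fun(mid))) hi <- mid else lo <- mid
  }
  hi
}

#' Activation threshold of one neuron
#'
#' Runs [bisect_threshold()] with [simulate_neuron()] as the spike oracle.
#' Thanks to the linearity of the volume-conduction problem, the field is
#' solved once per electrode for unit current and only the scalar amplitude
#' changes between simulations.
#'
#' @param morph a buildable `neuron_morphology`.
#' @param unit_potentials volts per ampere at compartment centers.
#' @param w a [stimulus_waveform()].
#' @param mem a [membrane_model()].
#' @param config a [sim_config()].
#' @param bracket a [bracket_config()].
#' @return threshold in uA (`NA` if not activated below the cap).
#' @export
neuron_threshold <- function(morph, unit_potentials,
                             w = stimulus_waveform(),
                             mem = membrane_model(),
                             config = sim_config(),
                             bracket = bracket_config()) {
  bisect_threshold(function(a)
    simulate_neuron(morph, unit_potentials, a, w, mem, config)$spike,
    bracket)
}

#' Pipeline configuration for array runs
#'
#' Gathers every tunable of the per-electrode pipeline; defaults reproduce
#' the study conditions (250 somas within 700 um, single cathodic-first
#' 0.45 ms/phase pulse, 0.1 uA bisection, thin-retina exclusion below
#' 100 um).
#'
#' @param n_somas somas per electrode population.
#' @param radius_um soma placement radius.
#' @param seed base seed; each electrode derives a per-electrode stream.
#' @param lloyd_iterations Lloyd relaxation iterations.
#' @param grid a [grid_spec()].
#' @param conduct a [conductivity_defaults()].
#' @param waveform a [stimulus_waveform()].
#' @param solver a [solver_config()].
#' @param sim a [sim_config()].
#' @param bracket a [bracket_config()].
#' @param membrane_path YAML membrane parameter file.
#' @param trajectory a [trajectory_params()].
#' @param plan a [section_plan()].
#' @param min_thickness_um thin-retina exclusion threshold.
#' @param thickness_fun optional thickness map passed to the geometry.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_somas = 250L, radius_um = 700, seed = 1L,
                       lloyd_iterations = 30L,
                       grid = grid_spec(), conduct = conductivity_defaults(),
                       waveform = stimulus_waveform(),
                       solver = solver_config(), sim = sim_config(),
                       bracket = bracket_config(),
                       membrane_path = NULL,
                       trajectory = trajectory_params(),
                       plan = section_plan(),
                       min_thickness_um = 100,
                       thickness_fun = NULL) {
  structure(list(n_somas = as.integer(n_somas), radius_um = radius_um,
                 seed = as.integer(seed),
                 lloyd_iterations = as.integer(lloyd_iterations),
                 grid = grid, conduct = conduct, waveform = waveform,
                 solver = solver, sim = sim, bracket = bracket,
                 membrane_path = membrane_path, trajectory = trajectory,
                 plan = plan, min_thickness_um = min_thickness_um,
                 thickness_fun = thickness_fun), class = "run_config")
}

# sample unit potentials at compartment centers, clamping points that leave
# the lateral grid to the boundary value (far-field, negligible potential)
unit_potentials_for <- function(morph, field) {
  pts <- as.matrix(morph$compartments[, c("x_um", "y_um", "z_um")])
  clamp <- function(v, g) pmin(pmax(v, g[1]), g[length(g)])
  pts[, 1] <- clamp(pts[, 1], field$xc)
  pts[, 2] <- clamp(pts[, 2], field$yc)
  pts[, 3] <- clamp(pts[, 3], field$zc)
  sample_potential(field, pts)
}

#' Per-neuron thresholds for one electrode site
#'
#' Builds the slab geometry, solves the unit field, places the soma
#' population, builds each morphology along its fiber trajectory and runs
#' the bisection threshold search, returning the per-neuron table for this
#' electrode. Neurons whose soma sits where the retina is thinner than the
#' soma depth are unbuildable; thin-retina exclusion (< `min_thickness_um`)
#' is applied by [electrode_threshold()].
#'
#' @param site an [electrode_site()] or site-table row list.
#' @param cfg a [run_config()].
#' @param field optionally re-use a solved `potential_field`.
#' @param model optionally re-use a built `tissue_model`.
#' @return A `threshold_table` data frame for one electrode with columns
#'   `electrode`, `neuron`, `soma_x_um`, `soma_y_um`, `threshold_uA`,
#'   `excluded`, `reason`.
#' @export
electrode_neuron_thresholds <- function(site, cfg = run_config(),
                                        model = NULL, field = NULL) {
  if (!inherits(site, "electrode_site"))
    site <- do.call(electrode_site, site[c("label", "erd_um", "thickness_um",
                                           "fibrosis_um")])
  if (is.null(model))
    model <- build_slab_geometry(site, grid = cfg$grid,
                                 conduct = cfg$conduct,
                                 thickness_fun = cfg$thickness_fun)
  if (is.null(field))
    field <- solve_unit_field(model, config = cfg$solver)
  mem <- if (is.null(cfg$membrane_path)) membrane_model() else
    membrane_model(cfg$membrane_path)
  eseed <- (cfg$seed * 131L +
              utils::head(utf8ToInt(site$label), 1)) %% .Machine$integer.max
  pop <- place_somas_lloyd(center = c(0, 0), radius_um = cfg$radius_um,
                           n = cfg$n_somas,
                           iterations = cfg$lloyd_iterations, seed = eseed)
  rows <- vector("list", cfg$n_somas)
  for (i in seq_len(cfg$n_somas)) {
    sxy <- pop$xy[i, ]
    traj <- axon_trajectory(sxy, cfg$trajectory)
    morph <- build_morphology(sxy, traj, model = model, plan = cfg$plan)
    if (!morph$buildable) {
      rows[[i]] <- data.frame(electrode = site$label, neuron = i,
                              soma_x_um = sxy[1], soma_y_um = sxy[2],
                              threshold_uA = NA_real_, excluded = TRUE,
                              reason = "unbuildable",
                              stringsAsFactors = FALSE)
      next
    }
    up <- unit_potentials_for(morph, field)
    thr <- neuron_threshold(morph, up, cfg$waveform, mem, cfg$sim,
                            cfg$bracket)
    rows[[i]] <- data.frame(electrode = site$label, neuron = i,
                            soma_x_um = sxy[1], soma_y_um = sxy[2],
                            threshold_uA = thr, excluded = FALSE,
                            reason = "", stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("threshold_table", "data.frame")
  tab
}

#' Electrode threshold with thin-retina exclusion
#'
#' Flags neurons whose soma sits where the retina has degenerated below
#' `min_thickness_um` (default 100 um), then returns the absolute minimum
#' activation threshold over the remaining included neurons — the
#' electrode-level prediction compared against perceptual thresholds.
#'
#' @param table per-neuron `threshold_table` for one electrode.
#' @param model the `tissue_model` the thresholds were computed in (supplies
#'   the thickness field); `NULL` skips re-evaluation of exclusions.
#' @param min_thickness_um exclusion threshold, micrometers.
#' @return list with `min_uA` (`NA` if every neuron is excluded or silent)
#'   and the updated `table`.
#' @export
electrode_threshold <- function(table, model = NULL,
                                min_thickness_um = 100) {
  if (!is.null(model)) {
    thick <- local_retinal_thickness(model, table$soma_x_um,
                                     table$soma_y_um)
    thin <- thick < min_thickness_um & !table$excluded
    table$excluded[thin] <- TRUE
    table$reason[thin] <- "thin_retina"
  }
  ok <- !table$excluded & !is.na(table$threshold_uA)
  min_uA <- if (any(ok)) min(table$threshold_uA[ok]) else NA_real_
  list(min_uA = min_uA, table = table)
}

#' Run the field-cable pipeline over a patient's array
#'
#' Applies the electrode inclusion rule ([include_electrode()]), then runs
#' geometry, field solve, population placement and bisection thresholds for
#' every included electrode. Per-electrode failures are caught and logged,
#' never aborting the whole run.
#'
#' @param patient a `site_table` data frame (e.g. from
#'   [generate_synthetic_patient()] or [read_measurements()]).
#' @param cfg a [run_config()].
#' @param progress print per-electrode progress lines.
#' @return A `threshold_table` over all neurons of all included electrodes,
#'   with attributes `electrode_summary` (data frame: electrode, erd_um,
#'   min threshold, counts) and `skipped` (excluded or failed electrodes
#'   with reasons).
#' @export
run_array <- function(patient, cfg = run_config(), progress = FALSE) {
  stopifnot(is.data.frame(patient))
  tabs <- list()
  summ <- list()
  skipped <- list()
  for (i in seq_len(nrow(patient))) {
    site <- site_from_row(patient, i)
    if (!include_electrode(site)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(electrode = site$label, reason = "inclusion_rule",
                   stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch({
      model <- build_slab_geometry(site, grid = cfg$grid,
                                   conduct = cfg$conduct,
                                   thickness_fun = cfg$thickness_fun)
      tab <- electrode_neuron_thresholds(site, cfg, model = model)
      et <- electrode_threshold(tab, model, cfg$min_thickness_um)
      list(tab = et$table, min = et$min_uA)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1]] <-
        data.frame(electrode = site$label,
                   reason = paste0("error: ", conditionMessage(res)),
                   stringsAsFactors = FALSE)
      next
    }
    tabs[[length(tabs) + 1]] <- res$tab
    summ[[length(summ) + 1]] <- data.frame(
      electrode = site$label, erd_um = site$erd_um,
      thickness_um = site$thickness_um,
      min_threshold_uA = res$min,
      n_neurons = nrow(res$tab), n_excluded = sum(res$tab$excluded),
      stringsAsFactors = FALSE)
    if (progress)
      message(sprintf("[%s] min threshold %.1f uA (%d/%d excluded)",
                      site$label, res$min, sum(res$tab$excluded),
                      nrow(res$tab)))
  }
  out <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(electrode = character(), neuron = integer(),
               soma_x_um = numeric(), soma_y_um = numeric(),
               threshold_uA = numeric(), excluded = logical(),
               reason = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("threshold_table", "data.frame")
  attr(out, "electrode_summary") <- if (length(summ)) do.call(rbind, summ)
    else NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
    else NULL
  out
}

#' Per-electrode summary of a threshold table
#'
#' @param table a `threshold_table` from [run_array()].
#' @return the `electrode_summary` attribute (electrode, geometry, minimum
#'   threshold, neuron counts).
#' @export
electrode_summary <- function(table) attr(table, "electrode_summary")
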