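#' Load a membrane model parameter set
#'
#' Channel maximal-conductance densities per section type, capacitance,
#' axial resistivity, reversal potentials and calcium-pool parameters for
#' the five-channel retinal ganglion cell membrane (Na, delayed-rectifier K,
#' A-type K, Ca, Ca-gated K, leak). The bundled default follows the
#' published mammalian RGC parameter lineage; alternate sets can be supplied
#' as YAML files with the same keys.
#'
#' @param path YAML parameter file (default: the bundled set).
#' @return list of class `membrane_model`.
#' @export
membrane_model <- function(path = system.file("extdata", "membrane_rgc.yaml",
                                              package = "fieldcable")) {
  p <- yaml::read_yaml(path)
  need <- c("cm_uF_cm2", "axial_resistivity_ohm_cm", "v_rest_mV", "ena_mV",
            "ek_mV", "cao_mM", "ca_rest_mM", "tau_ca_ms", "ca_diss_mM",
            "ca_shell_depth_um", "temp_C", "q10", "rate_ref_C", "densities")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("membrane parameter file missing key(s): ",
         paste(missing, collapse = ", "))
  for (sec in names(p$densities)) {
    d <- p$densities[[sec]]
    if (any(unlist(d[setdiff(names(d), "na_shift")]) < 0))
      stop("negative conductance density in ", sec)
    if (d$leak <= 0) stop("leak density must be positive in ", sec)
  }
  p$q_rate <- p$q10^((p$temp_C - p$rate_ref_C) / 10)
  structure(p, class = "membrane_model")
}

#' Stimulus waveform
#'
#' Charge-balanced biphasic rectangular current pulse(s), cathodic phase
#' first, matching the clinical stimulation protocol (0.45 ms per phase;
#' trains of five pulses at 20 Hz for perceptual testing, a single pulse by
#' default for threshold simulation).
#'
#' @param phase_ms duration of each phase (default 0.45).
#' @param gap_ms interphase gap (default 0).
#' @param n_pulses pulses per train (default 1).
#' @param period_ms pulse period within a train (default 50, i.e. 20 Hz).
#' @param cathodic_first logical; `FALSE` gives the polarity-reversed pulse.
#' @return list of class `stimulus_waveform`.
#' @export
stimulus_waveform <- function(phase_ms = 0.45, gap_ms = 0, n_pulses = 1L,
                              period_ms = 50, cathodic_first = TRUE) {
  stopifnot(phase_ms > 0, gap_ms >= 0, n_pulses >= 1,
            period_ms >= 2 * phase_ms + gap_ms)
  structure(list(phase_ms = phase_ms, gap_ms = gap_ms,
                 n_pulses = as.integer(n_pulses), period_ms = period_ms,
                 cathodic_first = isTRUE(cathodic_first)),
            class = "stimulus_waveform")
}

#' Dimensionless waveform scale
#'
#' -1 during cathodic phases, +1 during anodic phases, 0 otherwise; the
#' time integral over the train is zero (charge balance). Extracellular
#' potentials computed for unit injected current are multiplied by
#' `scale * amplitude`.
#'
#' @param t_ms time(s) since stimulus onset, ms.
#' @param w a [stimulus_waveform()].
#' @return numeric vector in \{-1, 0, +1\}.
#' @export
waveform_scale <- function(t_ms, w = stimulus_waveform()) {
  stopifnot(all(t_ms >= 0))
  tloc <- t_ms %% w$period_ms
  pulse_i <- floor(t_ms / w$period_ms)
  s1 <- if (w$cathodic_first) -1 else 1
  out <- numeric(length(t_ms))
  in_train <- pulse_i < w$n_pulses
  ph1 <- in_train & tloc < w$phase_ms
  ph2 <- in_train & tloc >= w$phase_ms + w$gap_ms &
    tloc < 2 * w$phase_ms + w$gap_ms
  out[ph1] <- s1
  out[ph2] <- -s1
  out
}

#' Simulation configuration
#'
#' @param dt_ms time step (default 0.005, must be <= 0.025).
#' @param t_end_ms simulated duration (default 3 ms: a single biphasic
#'   pulse plus time for spike propagation).
#' @param record_every store every k-th step (default 1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(dt_ms = 0.005, t_end_ms = 3, record_every = 1L) {
  if (dt_ms > 0.025) stop("dt_ms must be <= 0.025 ms")
  structure(list(dt_ms = dt_ms, t_end_ms = t_end_ms,
                 record_every = as.integer(record_every)),
            class = "sim_config")
}

# per-compartment absolute electrical quantities from a morphology
compartment_electrics <- function(morph, mem) {
  comp <- morph$compartments
  n <- nrow(comp)
  # membrane area: soma as sphere, others as cylinder side wall (cm^2)
  area <- ifelse(comp$section == "soma",
                 pi * (comp$diam_um * 1e-4)^2,
                 pi * comp$diam_um * 1e-4 * comp$L_um * 1e-4)
  cm <- mem$cm_uF_cm2 * area
  dens <- mem$densities
  pick <- function(ch) vapply(seq_len(n), function(i) {
    d <- dens[[comp$section[i]]]
    if (is.null(d)) stop("no densities for section ", comp$section[i])
    as.numeric(d[[ch]])
  }, numeric(1))
  g <- list(na = pick("na") * area, kdr = pick("kdr") * area,
            ka = pick("ka") * area, ca = pick("ca") * area,
            kca = pick("kca") * area, leak = pick("leak") * area)
  na_shift <- vapply(seq_len(n), function(i) {
    d <- dens[[comp$section[i]]]
    if (is.null(d$na_shift)) 0 else as.numeric(d$na_shift)
  }, numeric(1))
  # axial conductance between successive compartments (mS):
  # half-compartment resistances in series, R = 4 rho L / (pi d^2)
  rho <- mem$axial_resistivity_ohm_cm
  rhalf <- 4 * rho * (comp$L_um * 1e-4 / 2) / (pi * (comp$diam_um * 1e-4)^2)
  gax <- 1e3 / (rhalf[-n] + rhalf[-1])  # ohm -> mS
  vol_shell <- area * mem$ca_shell_depth_um * 1e-4  # cm^3
  list(area = area, cm = cm, g = g, gax = gax, vol_shell = vol_shell,
       na_shift = na_shift)
}

#' Simulate one RGC under extracellular stimulation
#'
#' Integrates the multicompartment cable system
#' `c_m dV_i/dt = sum_j g_ij ((V_j - V_i) + (Ve_j - Ve_i)) - I_ion,i`
#' with `Ve_i(t) = waveform_scale(t) * amplitude * unit_potential_i`
#' (extracellular potentials are computed once per electrode for unit
#' current and scale linearly with amplitude). Gating variables advance by
#' exponential (Rush-Larsen) updates and voltages by a backward-Euler
#' tridiagonal solve; the scheme is deterministic.
#'
#' @param morph a buildable `neuron_morphology`.
#' @param unit_potentials extracellular potential at each compartment
#'   center, volts per injected ampere (from [sample_potential()]).
#' @param amplitude_uA stimulus amplitude (magnitude of each phase), uA.
#' @param w a [stimulus_waveform()].
#' @param mem a [membrane_model()].
#' @param config a [sim_config()].
#' @param active_scale multiply all active (non-leak) conductances; 0 gives
#'   the passive membrane.
#' @return A `sim_result`: `t_ms`, voltage matrix `v_mV` (compartments x
#'   samples), the compartment table, spike flag and location from
#'   [detect_spike()].
#' @export
simulate_neuron <- function(morph, unit_potentials, amplitude_uA,
                            w = stimulus_waveform(), mem = membrane_model(),
                            config = sim_config(), active_scale = 1) {
  if (!morph$buildable) stop("morphology is unbuildable")
  comp <- morph$compartments
  n <- nrow(comp)
  stopifnot(length(unit_potentials) == n)
  el <- compartment_electrics(morph, mem)
  nsteps <- ceiling(config$t_end_ms / config$dt_ms)
  tgrid <- (seq_len(nsteps)) * config$dt_ms
  scale <- waveform_scale(tgrid, w)
  # V per A -> mV per uA: * 1e-6 A/uA * 1e3 mV/V
  ve_mv_per_ua <- unit_potentials * 1e-3
  res <- cable_integrate(
    cm = el$cm, gax = el$gax,
    gna = el$g$na * active_scale, gk = el$g$kdr * active_scale,
    ga = el$g$ka * active_scale, gca = el$g$ca * active_scale,
    gkca = el$g$kca * active_scale, gl = el$g$leak,
    vol_shell = el$vol_shell,
    ena = mem$ena_mV, ek = mem$ek_mV, v_rest = mem$v_rest_mV,
    cao = mem$cao_mM, ca_rest = mem$ca_rest_mM, tau_ca = mem$tau_ca_ms,
    ca_diss = mem$ca_diss_mM, na_shift = el$na_shift,
    ve_mv_per_ua = ve_mv_per_ua, scale = scale,
    amp_ua = amplitude_uA, dt = config$dt_ms,
    record_every = config$record_every, q_rate = mem$q_rate)
  out <- structure(list(t_ms = res$t, v_mV = res$v, compartments = comp,
                        amplitude_uA = amplitude_uA,
                        v_rest_mV = mem$v_rest_mV),
                   class = "sim_result")
  det <- detect_spike(out)
  out$spike <- det$spike
  out$spike_compartment <- det$compartment
  out$spike_time_ms <- det$t_ms
  out
}

#' Detect a propagating action potential
#'
#' A simulation counts as a spike when the membrane potential crosses 0 mV
#' upward in at least `min_run` consecutive distal-axon compartments after
#' stimulus onset — a propagation requirement that rejects local
#' depolarizations confined to the initial segment.
#'
#' @param res a `sim_result`.
#' @param min_run minimum number of consecutive distal-axon compartments
#'   that must cross 0 mV (default 3).
#' @return list with `spike` (logical), `compartment` (index of the first
#'   crossing compartment, or `NA`) and `t_ms` (first crossing time).
#' @export
detect_spike <- function(res, min_run = 3L) {
  distal <- which(res$compartments$section == "distal_axon")
  if (length(distal) == 0)
    return(list(spike = FALSE, compartment = NA_integer_, t_ms = NA_real_))
  v <- res$v_mV[distal, , drop = FALSE]
  crossed <- apply(v, 1, function(tr) any(tr[-1] > 0 & tr[-length(tr)] <= 0))
  r <- rle(crossed)
  ok <- any(r$values & r$lengths >= min_run)
  if (!ok)
    return(list(spike = FALSE, compartment = NA_integer_, t_ms = NA_real_))
  first <- distal[which(crossed)[1]]
  tr <- res$v_mV[first, ]
  ti <- which(tr[-1] > 0 & tr[-length(tr)] <= 0)[1]
  list(spike = TRUE, compartment = first, t_ms = res$t_ms[ti + 1])
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d compartments, %.2f ms at amplitude %.3g uA: %s\n",
              nrow(x$v_mV), max(x$t_ms), x$amplitude_uA,
              if (isTRUE(x$spike)) sprintf("spike (comp %d at %.2f ms)",
                                           x$spike_compartment,
                                           x$spike_time_ms) else "no spike"))
  invisible(x)
}

#' Export a simulation result to CSV
#'
#' @param res a `sim_result`.
#' @param path output file; columns are `t_ms` then one column per
#'   compartment.
#' @export
write_sim_result <- function(res, path) {
  m <- cbind(t_ms = res$t_ms, t(res$v_mV))
  colnames(m) <- c("t_ms", paste0("c", seq_len(nrow(res$v_mV))))
  write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
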