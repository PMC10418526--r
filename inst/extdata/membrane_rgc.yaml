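# Retinal ganglion cell membrane parameters (Fohlmeister-Miller lineage
# five-channel model: Na, delayed-rectifier K, A-type K, Ca, Ca-gated K,
# plus leak), mammalian regional density profile with a dense sodium-channel
# band at the axon initial segment. Gating rates are Q10-scaled from their
# reference temperature to body temperature. Leak reversal is solved at run
# time so that v_rest_mV is an exact resting equilibrium.
units:
  density: mS/cm2
  capacitance: uF/cm2
  axial_resistivity: ohm.cm
  voltage: mV
  concentration: mM
  time: ms
  temperature: C
cm_uF_cm2: 1.0
axial_resistivity_ohm_cm: 110
v_rest_mV: -65
ena_mV: 60
ek_mV: -75
cao_mM: 1.8
ca_rest_mM: 0.0001
tau_ca_ms: 1.5
ca_diss_mM: 0.001
ca_shell_depth_um: 0.1
temp_C: 37
rate_ref_C: 22
q10: 2.0
# na_shift: hyperpolarizing shift (mV) of Na activation, the low-threshold
# axonal (Nav1.6-like) channel isoform of initial segment and axon
densities:
  dendrite:       {na: 40,   kdr: 12, ka: 36, ca: 2.0, kca: 0.05,  leak: 0.05}
  soma:           {na: 100,  kdr: 30, ka: 54, ca: 1.5, kca: 0.065, leak: 0.05}
  axon_hillock:   {na: 300,  kdr: 50, ka: 54, ca: 1.5, kca: 0.065, leak: 0.5,
                   na_shift: -2.5}
  sodium_band:    {na: 2000, kdr: 120, ka: 0, ca: 1.5, kca: 0.065, leak: 0.5,
                   na_shift: -5}
  narrow_segment: {na: 200,  kdr: 30, ka: 0,  ca: 1.5, kca: 0.065, leak: 0.5,
                   na_shift: -5}
  distal_axon:    {na: 150,  kdr: 30, ka: 0,  ca: 0,   kca: 0,     leak: 0.5,
                   na_shift: -5}
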