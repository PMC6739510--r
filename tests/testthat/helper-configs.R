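# shared small fixtures; all sizes kept modest so the suite stays fast

ref_geom <- function() trabecula_geometry(1.8, 0.26)
ref_vgeom <- function() ventricle_geometry(L_ref_mm = 1.8)

# replay validation setup at body pacing (fast twitch completes within 0.2 s)
replay_cfg <- function(n_beats = 3, burn_in = 10, dt = 5e-5, decim = 10,
                       windkessel = wk_preset("normotensive"),
                       stim_hz = 5) {
  sim_config(windkessel = windkessel,
             cycle = cycle_policy(stim_hz = stim_hz),
             muscle = replay_muscle(t_rise = 0.012, t_fall = 0.035),
             n_beats = n_beats, burn_in_beats = burn_in,
             dt = dt, decimation = decim)
}

hill_cfg <- function(n_beats = 6, burn_in = 10, stim_hz = 5,
                     windkessel = wk_preset("normotensive"),
                     temperature = "body", decim = 10) {
  sim_config(windkessel = windkessel,
             cycle = cycle_policy(stim_hz = stim_hz),
             muscle = hill_muscle(hill_params(temperature = temperature)),
             n_beats = n_beats, burn_in_beats = burn_in,
             decimation = decim)
}

peak_normalised_diff <- function(a, b) {
  max(abs(a - b)) / max(abs(a))
}
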