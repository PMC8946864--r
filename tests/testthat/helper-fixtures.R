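# shared fixtures: the standard implants and hot-beverage load
implant_A <- preset_model("implant_A")
implant_B <- preset_model("implant_B")
hot_load <- function(t0 = 2) thermal_load(t_hot = 60, t_body = 37, exposure_time = t0)

# closed-form mode amplitude scaled to C_n, for oracle comparisons
closed_form_Cn <- function(n, t, load, model) {
  (2 * delta_t(load) / pi) * mode_amplitude(rep(n, length(t)), t, load, model)
}
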