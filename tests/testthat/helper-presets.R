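# shared fixtures built in code

vitro <- ca_preset("in_vitro")
vivo <- ca_preset("in_vivo")
vitro_dw <- ca_preset("in_vitro", potential = "double_well")
vivo_dw <- ca_preset("in_vivo", potential = "double_well")

# equal-amplitude variant sharing all non-amplitude constants
equal_amp_params <- function(C, potential = "flat") {
  plasticity_params(C, C, vitro$tau_ca, vitro$theta_d, vitro$theta_p,
                    vitro$gamma_d, vitro$gamma_p, vitro$sigma,
                    vitro$tau_rho, potential = potential)
}
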