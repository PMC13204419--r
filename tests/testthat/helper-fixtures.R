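# shared fixtures: forearm-skin optics at the probe wavelengths and the
# published repeat-measurement triples used as numeric anchors

skin_optics <- function(wavelength = 730) {
  musp <- c(`730` = 1.41, `810` = 1.23, `855` = 1.13)
  optical_properties(mu_a = 0.01,
                     mu_s_prime = unname(musp[as.character(wavelength)]))
}

# repeat triples (mm^-1) and their reported means
repeat_triples <- list(
  consecutive = list(values = c(0.142, 0.141, 0.143), mean = 0.142),
  volunteer2_730 = list(values = c(0.148, 0.149, 0.149), mean = 0.149),
  volunteer8_730 = list(values = c(0.249, 0.239, 0.241), mean = 0.243)
)

# attenuation coefficients of the low- and high-attenuation subjects at
# 855 nm, used for the fluence-map comparisons
mueff_low <- 0.136
mueff_high <- 0.252

default_spectra <- function() hemoglobin_extinction()
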