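# shared fixtures: small noise-free and noisy synthetic datasets

noiseless_config <- function(...) {
  synth_config(noise_flux = 0, noise_met = 0, rain_every_days = 0, ...)
}

# standard daytime/physiology filter used by the recovery tests
daytime_mask <- function(d) {
  !is.na(d$PPFD) & d$PPFD > 200 & !is.na(d$LE) & d$LE > 0 &
    !is.na(d$Da) & d$Da > 0.01
}

derive_Gsw <- function(d, truth) {
  ac <- aerodynamic_conductance(d, zr = truth$zr, zh = truth$zh,
                                Gb_model = "Thom", Gam_model = "ustar")
  surface_conductance(Rn = d$Rn, LE = d$LE, Da = d$Da, Ta = d$Ta,
                      p = d$p, Gah = ac$Gah)$Gsw_mol
}
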