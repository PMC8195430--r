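# Template parameter file for the hb_yang scenario.
#
# The Hunchback-Bicoid reaction-diffusion model requires the parameter values
# published by Yang et al. (2020), "Dynamics of Hunchback translation in
# real-time and at single-mRNA resolution in the Drosophila embryo"
# (the quantitative Hb boundary-shift study). Those values are NOT bundled
# with this package: fill in every field below from that source before
# running `scenario("hb_yang", param_file = ...)`. No defaults are assumed.
#
# Units: concentrations and rates in the source publication's nondimensional
# units; lengths as fractions of embryo length unless stated otherwise.

[model]
family = "hb"
# domain length (embryo length in the model's length units)
L =

[params]
# maximal Bcd-driven Hb production rate
alpha_b =
# maximal Hb self-activation production rate
alpha_h =
# Bcd concentration at half-maximal activation
b0 =
# Hb concentration at half-maximal self-activation
h0 =
# Bcd Hill coefficient
nb =
# Hb Hill coefficient
nh =
# Hb first-order decay rate
beta =
# Hb diffusivity
D =

[gradient1]
kind = "bcd"
# Bcd gradient amplitude
bm =
# Bcd gradient length constant
lam =
# rate of temporal decrease in Bcd after onset
omega0 =
# onset time of Bcd decay
t0 =
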