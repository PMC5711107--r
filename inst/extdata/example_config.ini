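# Example configuration: 13 MeV-class beam (nominal 13 MeV, incident
# mean energy 13.99 MeV) on a generic dual-foil beamline with an 80 um
# tantalum primary foil and a 25-segment aluminum Gaussian secondary
# foil (t0 = 0.6 cm, sigma = 1.44 cm). Distances are generic defaults,
# not those of any specific accelerator.

[beam]
energy = 13.99
mode = incident_mean
ep0_offset = 0

[geometry]
d_window_primary = 3
d_primary_secondary = 15
d_secondary_iso = 85
SAD = 100
calc_depth = 2

[window]
material = nickel
thickness = 0.0125

[primary_foil]
material = tantalum
thickness = 0.008

[secondary_foil]
mode = gaussian
material = aluminum
t0 = 0.6
sigma = 1.44
n_segments = 25
r_max = 3.65
file =

[calculation]
half_range = 30
n_rho = 100
n_theta = 100
n_profile = 60
kernel = conditional
t_secondary = fluence_weighted

[xray]
include = true
a = -0.035
b = 15.77
c = 0.016

[flatness]
range = 14.6
criterion = 3
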