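# Reference parameters of the subcutaneous hydrogel depot model.
# Units are fixed: lengths in mm, times in day, intensities on the
# dimensionless scale set by the maximum observable intensity.

[source]
A = 500       # scaled release strength (intensity/day)
k = 1.5       # Weibull shape factor
lam = 10      # Weibull scale parameter (day)
T = 1.5       # phase lag (day)
R = 0.42      # gel radius: inner radius of a modified gauge-18 needle (mm)

[initial]
c0 = 0.1      # baseline scaled intensity
c1 = 0.8      # excess amplitude at the injection centre
a = 0.16      # radial decay coefficient (mm^-alpha)
alpha = 1.5   # radial power

[transport]
D = 4.32      # apparent in vivo diffusivity (mm^2/day)

[fd]
dr = 0.05     # finite-difference spacing (mm)
dt = 0.01     # time step (day)
r_max = 120   # domain truncation (mm); keeps the 60-day horizon outflow-free
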