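# Shared fixtures: the standard parameter set and a few derived constants
# used across test files. All built in code - no stored data.

default_geometry <- gut_geometry()          # 2.85 m x 1.8 cm, f = 12
default_solute <- gut_solute()              # glucose: r0 = 0.38 nm, 180 g/mol
water_fluid <- gut_fluid(0.001)             # 1 mPa s

# residence time L/u (s)
t_res <- default_geometry$length_L / default_geometry$mean_velocity_u

# absorption rate constant at 1 mPa s, frozen from independent hand
# evaluation of the Stokes-Einstein + Sherwood chain
k_a_water <- 1.813264e-4

# a coarse-but-valid grid to keep solver tests quick
coarse_grid <- build_grid(default_geometry, n_cells = 100)
default_grid <- build_grid(default_geometry, n_cells = 285)
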