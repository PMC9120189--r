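# Material constants for the core-shell magnetoelectric particle model.
# Units are as conventionally tabulated: conductivity S/m, saturation
# magnetostriction ppm, density kg/m^3, saturation magnetization A/m,
# Young's modulus GPa, elasticity matrix GPa (flat, upper triangle,
# column-major Voigt 11,22,33,23,13,12), coupling matrix C/m^2 (3 x 6).
# "~" marks constants that do not apply to a material.
barium_titanate:
  sigma: 1.0e-7
  chi0: ~
  lambda_s_ppm: ~
  density: 5700
  Ms: ~
  poisson: ~
  eps_r: [1115.1, 1115.1, 1251.3]
  youngs_GPa: ~
  elasticity_voigt_GPa: [150.377, 656.308, 150.377, 65.9391, 65.9391, 145.521,
                         0, 0, 0, 43.8596,
                         0, 0, 0, 0, 43.8596,
                         0, 0, 0, 0, 0, 42.3729]
  coupling_voigt:
    - [0, 0, -4.32015, 0, 0, -4.32015]
    - [0, 0, 17.3624, 0, 11.4035, 0]
    - [11.4035, 0, 0, 0, 0, 0]
cobalt_ferrite:
  sigma: 4.2e-5
  chi0: 70
  lambda_s_ppm: 315
  density: 6060
  Ms: 181800
  poisson: 0.33
  eps_r: [9.0355, 9.0355, 10.5037]
  youngs_GPa: 188.4
  elasticity_voigt_GPa: ~
  coupling_voigt: ~
electrolyte:
  # cerebrospinal-fluid-like medium surrounding the particle
  sigma: 1.79
  chi0: 0
  lambda_s_ppm: ~
  density: 1007
  Ms: ~
  poisson: ~
  eps_r: [80, 80, 80]
  youngs_GPa: ~
  elasticity_voigt_GPa: ~
  coupling_voigt: ~
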