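# Reference head-impact populations: class-conditional moments, class
# sizes and within-class axis dependence used by the synthetic generators.
# Accelerations in g (linear) and rad/s^2 (rotational). rho is the
# Gaussian-copula correlation between the two axes (not published for
# either dataset; see package documentation for the rationale).
hits:
  subconcussive:
    mean_linear: 26
    sd_linear: 19
    mean_rotational: 1072
    sd_rotational: 850
    rho: 0.55
    n_impacts: 62974
  concussive:
    mean_linear: 104
    sd_linear: 30
    mean_rotational: 4726
    sd_rotational: 1931
    rho: 0.35
    n_impacts: 37
nfl:
  subconcussive:
    mean_linear: 57
    sd_linear: 22
    mean_rotational: 4029
    sd_rotational: 1438
    rho: 0.55
    n_impacts: 33
  concussive:
    mean_linear: 98
    sd_linear: 28
    mean_rotational: 6432
    sd_rotational: 1813
    rho: 0.35
    n_impacts: 25
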