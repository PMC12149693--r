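# Default prompt-gamma line catalogue for proton irradiation of PMMA-like
# targets. Excitation-function parameters (EMG in proton kinetic energy:
# area A in mb*MeV, centroid mu, width sigma, decay constant tau in MeV,
# clipped below `threshold`) are editable configuration fitted to published
# excitation functions; they are per nucleus of `target_symbol`.
- line:
    line_id: 12C_2p_0p
    emitter: 12C
    transition: 2+->0+
    energy_mev: 4.44
    reaction: 12C(p,p')12C*
    target_symbol: C
    single_photon_allowed: true
    secondary: false
    yield_per_primary: 0.0
  xsec:
    A: 11000.0
    mu: 10.0
    sigma: 3.0
    tau: 35.0
    threshold: 5.0
    valid_range: [0.0, 250.0]
- line:
    line_id: 16O_3m_0p
    emitter: 16O
    transition: 3-->0+
    energy_mev: 6.13
    reaction: 16O(p,p')16O*
    target_symbol: O
    single_photon_allowed: true
    secondary: false
    yield_per_primary: 0.0
  xsec:
    A: 4500.0
    mu: 12.0
    sigma: 2.5
    tau: 22.0
    threshold: 8.6
    valid_range: [0.0, 250.0]
- line:
    # E0 transition between two spin-zero states: single-photon emission is
    # forbidden (internal conversion only). Kept in the catalogue so the
    # emission model can prove it never emits it.
    line_id: 16O_E0_6.05
    emitter: 16O
    transition: 0+->0+
    energy_mev: 6.05
    reaction: 16O(p,p')16O*
    target_symbol: O
    single_photon_allowed: false
    secondary: false
    yield_per_primary: 0.0
  xsec:
    A: 1500.0
    mu: 12.0
    sigma: 2.5
    tau: 20.0
    threshold: 8.3
    valid_range: [0.0, 250.0]
- line:
    # produced by thermalised secondary neutrons capturing on hydrogen, not
    # by the proton-step model: injected via a constant per-primary yield
    line_id: 1H_ncap
    emitter: 2H
    transition: capture
    energy_mev: 2.22
    reaction: 1H(n,g)2H
    target_symbol: H
    single_photon_allowed: true
    secondary: true
    yield_per_primary: 0.002
- line:
    # positron annihilation, non-nuclear line
    line_id: annihilation
    emitter: e+e-
    transition: annihilation
    energy_mev: 0.511
    reaction: e+e- -> 2g
    target_symbol: C
    single_photon_allowed: true
    secondary: true
    yield_per_primary: 0.004
- line:
    line_id: 10B_1st
    emitter: 10B
    transition: 1st excited
    energy_mev: 0.718
    reaction: 12C(p,x)10B*
    target_symbol: C
    single_photon_allowed: true
    secondary: false
    yield_per_primary: 0.0
  xsec:
    A: 3000.0
    mu: 35.0
    sigma: 8.0
    tau: 40.0
    threshold: 20.0
    valid_range: [0.0, 250.0]
- line:
    line_id: 11B_2.125
    emitter: 11B
    transition: 1/2- -> 3/2-
    energy_mev: 2.125
    reaction: 12C(p,2p)11B*
    target_symbol: C
    single_photon_allowed: true
    secondary: false
    yield_per_primary: 0.0
  xsec:
    A: 2000.0
    mu: 30.0
    sigma: 7.0
    tau: 45.0
    threshold: 16.0
    valid_range: [0.0, 250.0]
- line:
    line_id: 14N_2.313
    emitter: 14N
    transition: 0+->1+
    energy_mev: 2.313
    reaction: 16O(p,x)14N*
    target_symbol: O
    single_photon_allowed: true
    secondary: false
    yield_per_primary: 0.0
  xsec:
    A: 1200.0
    mu: 28.0
    sigma: 6.0
    tau: 40.0
    threshold: 15.0
    valid_range: [0.0, 250.0]
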