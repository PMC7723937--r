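# FRPVE cartilage material constants. Moduli in MPa, eta in MPa*s,
# permeability k in 1e-15 m^4/(N*s) (converted internally to mm^4/(N*s)).
# Fluid fraction profile: n_f(h_z) = nf_surface - nf_slope * h_z,
# with h_z the normalized depth (0 articular surface, 1 bone interface).
femoral:
  e_m: 0.215
  e_0: 0.92
  e_eps: 150.0
  nu_m: 0.15
  eta: 1062.0
  k_perm: 6.0
  nf_surface: 0.8
  nf_slope: 0.15
tibial:
  e_m: 0.106
  e_0: 0.18
  e_eps: 23.06
  nu_m: 0.15
  eta: 1062.0
  k_perm: 18.0
  nf_surface: 0.8
  nf_slope: 0.15
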