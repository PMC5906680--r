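{
  "required": {
    "meta": ["seed", "package"],
    "mobility": ["fraction_mobile", "fraction_immobile", "n_trajectories"],
    "diffusion": ["D_components", "weights", "n_jumps"],
    "stepcount": ["histogram", "n_traces"],
    "piccs": ["alpha", "sigma_c_nm", "rho_um2"],
    "kinetics": ["ka", "kd", "k_obs", "KD"]
  }
}
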