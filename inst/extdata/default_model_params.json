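{
  "comment": "Default model parameters. gamma, n_lineages, t_end follow the source study; sigma, K_hill, m_hill and alpha were calibrated once (grid scan, 300 simulations per cell) so that a single dominant MPC-like lineage emerges in >=95% of baseline threshold-version runs at a final size of ~100 cells; K_hill and m_hill take different values in the two inhibition variants.",
  "shared": {
    "n_lineages": 5,
    "r": 0.05,
    "gamma": 0.5,
    "sigma": 0.05,
    "t_end": 120,
    "dt": 0.05,
    "noise_coupling": "multiplicative"
  },
  "threshold": {
    "K_hill": 2,
    "m_hill": 4,
    "alpha": 0.5
  },
  "mutual": {
    "K_hill": 10,
    "m_hill": 6,
    "alpha": 0.5
  }
}
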