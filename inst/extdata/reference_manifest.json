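{
  "zn_zn_cut_nm": 0.5,
  "o_zn_cut_nm": 0.25,
  "zn_water_cut_nm": 0.2,
  "hb_d_cut_nm": 0.35,
  "hb_angle_cut_deg": 30,
  "dt_ps": 5,
  "quantiles": [0.05, 0.25, 0.5, 0.75, 0.95],
  "temperature_k": 300,
  "viscosity_pa_s": 8.5e-04,
  "freq_1h_mhz": 400.13,
  "r_ch_nm": 0.109
}
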