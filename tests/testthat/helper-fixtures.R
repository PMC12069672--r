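# Shared fixtures: the broccoli base case and values frozen from an
# independent arbitrary-precision evaluation of the closed forms.

base_p <- respiration_params()
base_geom <- box_geometry()
base_diff <- diffusion_params()
base_ctl <- control_settings()

frozen <- list(
  vmax_10 = 32.4741056074304,     # arrhenius_factor(2.76e17, 8.63e4, 10)
  rmin_10 = 9.63284338731216,     # arrhenius_factor(9.90e19, 1.03e5, 10)
  resp_specific_10 = 13.0904525945312,  # O2 3%, CO2 15%, 10 degC
  resp_box_10 = 209.4472415125,         # x 16 kg
  vf = 0.0547619047619048,        # 0.07 - 16/1050
  o2_after_off_1h = 3.02365053589292,   # k_off, vf, start 3%, 3600 s
  vol_off_1h = 12.9514839413598,  # mL over the same interval
  bof_base = 47.919042413545,     # base BOF at 10 degC
  trough_20 = 1.509529608,        # setpoint-kinetics limit-cycle minimum
  trough_5 = 2.844274116
)

# registry whose only uncertain parameter is `keep` (all other errors zeroed)
single_error_registry <- function(keep) {
  reg <- broccoli_params()
  reg$abs_error[reg$name != keep] <- 0
  reg$pct_error <- reg$abs_error / reg$base * 100
  reg
}
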