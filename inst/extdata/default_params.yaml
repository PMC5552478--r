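# Default trait-plant fitness parameters for the durability simulator.
#
# The susceptible-homozygote fitness on each transgenic cotton is derived
# from cotton leaf bioassay efficacy against the susceptible SCD strain
# (w_ss = 1 - efficacy/100, upper end of the printed range):
#   Bt cotton efficacy   79.4%  -> bt_w_ss   = 0.206
#   RNAi cotton efficacy 66%    -> rnai_w_ss = 0.34
# Resistant homozygotes are unaffected by their trait plant (w_rr = 1).
# Edit or replace this file to drop in fitness values transcribed from a
# published parameter table; scenario_presets(params = "<path>") reads it.
bt_init_r_freq: 0.05
bt_h: 0.5
bt_w_ss: 0.206
bt_w_rr: 1.0
rnai_init_r_freq: 0.001
rnai_w_ss: 0.34
rnai_w_rr: 1.0
generations_per_year: 3
resistance_threshold: 0.5
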