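# Example tracker configuration (see read_fusion_config); values are SI.
method = B
Ts = 0.02
sigma_g = 0.0174533    # 1 deg/s
sigma_a = 0.0981       # 10 mg
sigma_w = 0.14715      # 15 mg
sigma_v = 0.15
lambda_g = 1.4715      # 150 mg
rest_window = 1.0
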