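larmor_hz = 1e+09
gamma = 267522187.44

[[spin]]
position = [0, 0, 0]
shift_ppm = -0.1

[[spin]]
position = [0, 0, 1.75]
shift_ppm = 0.2

[[spin]]
position = [3, 0, 0]
shift_ppm = 0.7
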