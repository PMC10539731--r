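larmor_hz = 851500000
gamma = 267522187.44

[[spin]]
position = [0, 0, 0]
shift_ppm = 4.4

[[spin]]
position = [0, 0, 1.6]
shift_ppm = 3.9

[[spin]]
position = [2.20827765884688, 0, 0.803747336815322]
shift_ppm = 4.1
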