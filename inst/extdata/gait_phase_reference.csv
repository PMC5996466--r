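metric,Normal,NC_80,NC_100,NC_120,C_80,C_100,C_120
left_swing,42.22,42.00,41.67,42.00,38.00,41.22,43.00
right_swing,41.00,41.78,40.67,41.33,37.89,40.89,41.33
swing_diff,1.22,0.22,1.00,0.67,0.11,0.33,1.67
left_stance,57.78,58.00,58.33,58.00,62.00,58.78,57.00
right_stance,59.00,58.22,59.33,58.67,62.11,59.11,58.67
stance_diff,-1.22,-0.22,-1.00,-0.67,-0.11,-0.33,-1.67
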