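metric,Normal,NC_80,NC_100,NC_120,C_80,C_100,C_120
left_preswing,9.51,9.09,9.97,8.86,11.21,9.57,9.35
left_initial_swing,13.00,13.22,12.78,13.22,11.33,13.56,14.11
left_midswing,12.89,12.22,13.78,13.78,11.00,13.78,15.00
left_terminal_swing,16.33,16.56,15.11,15.00,15.67,14.89,13.89
left_loading_response,9.27,9.13,9.69,8.80,10.90,9.32,9.32
left_midstance,19.89,19.56,20.11,19.78,18.11,19.22,21.33
left_terminal_stance,19.11,20.22,18.56,20.56,21.78,19.67,17.00
right_preswing,9.19,9.21,9.86,9.40,11.16,9.37,9.30
right_initial_swing,13.78,13.33,13.00,13.00,10.78,12.44,15.00
right_midswing,14.44,13.89,13.89,14.44,11.22,13.33,14.56
right_terminal_swing,12.78,14.56,13.78,13.89,15.89,15.11,11.78
right_loading_response,9.59,9.01,9.80,9.26,10.95,9.52,9.36
right_midstance,19.89,19.33,19.11,20.00,18.78,19.44,21.78
right_terminal_stance,20.33,20.67,20.56,20.00,21.22,20.78,18.22
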