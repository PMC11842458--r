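association,K,NE,N,estimate,ci_low,ci_high,Q,df,I2,I2_low,I2_high
r_x1y1,48,146,19187,-0.339,-0.378,-0.298,49.2,47,0,0,41.7
r_x2y2,37,127,15737,-0.398,-0.442,-0.352,39.9,36,0,0,50.4
r_x1x2,39,133,15878,0.572,0.512,0.626,38.7,38,0,0,41.6
r_y1y2,46,140,19046,0.587,0.540,0.630,44.8,45,0,0,36.8
r_x1y2,46,140,19046,-0.266,-0.300,-0.232,43.3,45,0,0,34.5
r_x2y1,39,133,15878,-0.273,-0.312,-0.233,35.8,38,0,0,35.7
b_x_lagged,46,140,19046,-0.079,-0.096,-0.062,47.6,45,0,0,48.9
b_x_reverse,46,140,19046,-0.202,-0.236,-0.167,44.8,45,0,0,37.8
b_x_change,46,140,19046,0.083,0.054,0.112,46.1,45,0,0,40.8
b_y_lagged,39,133,15878,-0.088,-0.102,-0.075,56.8,38,0,0,84.0
b_y_reverse,39,133,15878,-0.202,-0.243,-0.161,48.3,38,0,0,60.7
b_y_change,39,133,15878,0.068,0.043,0.094,44.5,38,0,0,57.9
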