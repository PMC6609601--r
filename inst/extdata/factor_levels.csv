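factor,v1,v2,v3,v4,v5,v6
rotation_angle,180,192,204,216,228,240
vertical_angle,-10,-9,-8,-7,-6,-5
frd,25,27,29,31,33,35
beam_width,0.20,1.06,1.92,2.78,3.64,4.50
beam_height,4.80,5.84,6.88,7.92,8.96,10.00
filtration,2.51,2.57,2.63,2.69,2.75,2.81
kvp,57,60,63,66,69,72
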