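"learning_rate","mean_criterion","sd_criterion"
0,-0.000145155750713914,0.0758482761432332
0.002,0.0574785497388047,0.075771810003781
0.005,0.146576240109734,0.07634586999298
0.01,0.293499553797703,0.0811112672865036
0.015,0.444188983981214,0.0831362361968579
0.02,0.593784388172258,0.0933622183768952
0.03,0.888777905963411,0.111495538318549
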