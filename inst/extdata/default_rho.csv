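,left_P,left_M,left_A,right_P,right_M,right_A
left_P,1,0.45,-0.39,-0.8,-0.45,-0.1
left_M,0.45,1,0.31,-0.45,-0.5,-0.25
left_A,-0.39,0.31,1,0.46,0.1,-0.2
right_P,-0.8,-0.45,0.46,1,0.5,0.25
right_M,-0.45,-0.5,0.1,0.5,1,0.55
right_A,-0.1,-0.25,-0.2,0.25,0.55,1
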