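fov,x_global_px,y_global_px
1,0,0
2,150,0
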