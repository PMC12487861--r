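fov,cell_ID,CenterX_local_px,CenterY_local_px,cell_type
1,1,91.480000000000004,45.770000000000003,IL36G_KC
1,2,93.709999999999994,71.909999999999997,regTh17
1,3,28.609999999999999,93.469999999999999,Treg
1,4,83.040000000000006,25.539999999999999,Th17
1,5,64.170000000000002,46.229999999999997,NKT
2,1,51.909999999999997,94,IL36G_KC
2,2,73.659999999999997,97.819999999999993,regTh17
2,3,13.470000000000001,11.75,Treg
2,4,65.700000000000003,47.5,Th17
2,5,70.510000000000005,56.030000000000001,NKT
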