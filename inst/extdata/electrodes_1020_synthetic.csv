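label,x,y,z
Fpz,0,87.497,28.43
Fz,0,54.076,74.43
Cz,0,0,92
Pz,0,-54.076,74.43
Oz,0,-87.497,28.43
Fp1,-27.038,83.215,28.43
Fp2,27.038,83.215,28.43
F7,-70.787,51.43,28.43
F8,70.787,51.43,28.43
T7,-87.497,0,28.43
T8,87.497,0,28.43
P7,-70.787,-51.43,28.43
P8,70.787,-51.43,28.43
C3,-54.076,0,74.43
C4,54.076,0,74.43
F3,-39.839,59.378,57.889
F4,39.839,59.378,57.889
P3,-39.839,-59.378,57.889
P4,39.839,-59.378,57.889
FCz,0,28.43,87.497
C1,-28.43,0,87.497
C2,28.43,0,87.497
F1,-20.499,58.379,68.086
F2,20.499,58.379,68.086
F5,-56.923,57.017,44.416
F6,56.923,57.017,44.416
FC3,-50.006,31.617,70.454
FC4,50.006,31.617,70.454
FC1,-25.986,31.005,82.628
FC2,25.986,31.005,82.628
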