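mz,intensity
791.24,35
953.30,110
1085.34,240
1099.35,60
1115.36,45
1129.33,80
1247.39,95
1393.45,150
1409.44,70
1423.42,90
1555.50,40
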