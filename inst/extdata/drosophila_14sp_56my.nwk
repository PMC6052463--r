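((Dvir:32,Dmoj:32):24,((Dwil:30,(Dsal:10,Daus:10):20):14,((Dana:15,Dbip:15):12,(Dkik:22,(Dbia:15,((Dyak:8,Dere:8):3,(Dmel:6,(Dsim:2,Dsec:2):4):5):4):7):5):17):12);
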