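variant = mrna
k1m = 42
Kmm = 1
keff = 1
k1dm = 21
k1 = 2.3999999999999999
k2a = 2.3999999999999999
k2b = 60
k5am = 6
k5bm = 120
k5cm = 200
J5c = 202
J5 = 0.29999999999999999
n = 4
k5dm = 21
k5a = 2.1000000000000001
k6 = 6
k7 = 60
J7 = 0.01
k8 = 30
J8 = 0.01
Mad = 1
k3m = 42
k3dm = 21
k3a = 3
k3dt = 6
k3 = 60
k3b = 315
J3 = 0.040000000000000001
J4 = 0.040000000000000001
k4 = 1470
k9 = 6
k10 = 1.2
k11 = 16
k12 = 80
k13 = 1.6000000000000001
GF = 2
cycb_div_threshold = 0.10000000000000001
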