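variant = mrna
k1m = 1.8741887515286486
Kmm = 1
keff = 1
k1dm = 0.93709437576432431
k1 = 0.10709650008735135
k2a = 0.10709650008735135
k2b = 2.6774125021837833
k5am = 0.26774125021837841
k5bm = 5.3548250043675667
k5cm = 200
J5c = 202
J5 = 0.29999999999999999
n = 4
k5dm = 0.93709437576432431
k5a = 0.093709437576432436
k6 = 0.26774125021837841
k7 = 2.6774125021837833
J7 = 0.01
k8 = 1.3387062510918917
J8 = 0.01
Mad = 1
k3m = 1.8741887515286486
k3dm = 0.93709437576432431
k3a = 0.13387062510918921
k3dt = 0.26774125021837841
k3 = 2.6774125021837833
k3b = 14.056415636464864
J3 = 0.040000000000000001
J4 = 0.040000000000000001
k4 = 48.485728449464112
k9 = 0.26774125021837841
k10 = 0.053548250043675673
k11 = 0.71397666724900899
k12 = 3.5698833362450451
k13 = 0.071397666724900902
GF = 2
cycb_div_threshold = 0.10000000000000001
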