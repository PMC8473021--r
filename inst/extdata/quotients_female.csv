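variable,quotient,rank
X07,1.0126,1
X14,1.0055,2
X08,1.0044,3
X12,1.0025,4
X19,1.0007,5
X20,0.9999,6
X10,0.9986,7
X13,0.9982,8
X03,0.9965,9
X01,0.9956,10
X18,0.9956,11
X06,0.9913,12
X05,0.9894,13
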