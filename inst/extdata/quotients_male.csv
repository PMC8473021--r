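variable,quotient,rank
X10,1.0544,1
X14,1.0354,2
X08,1.0254,3
X12,1.0216,4
X07,1.0214,5
X18,1.0162,6
X13,1.0127,7
X15,1.0094,8
X11,1.0037,9
X04,1.0007,10
X02,1.0007,11
X17,0.9958,12
X19,0.9934,13
X03,0.9900,14
X05,0.9821,15
X16,0.9806,16
X06,0.9253,17
X01,0.9193,18
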