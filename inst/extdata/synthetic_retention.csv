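system,pct_acn,tr_min,t0_min
XBridge,60,4.289,1
IAM,10,45.668,1
IAM,20,26.119,1
IAM,30,15.125,1
IAM,40,8.943,1
IAM,50,5.467,1
PLRP-S,50,6.012,1
PLRP-S,60,4.631,1
PLRP-S,70,3.63,1
PLRP-S,80,2.905,1
PLRP-S,90,2.38,1
PLRP-S,100,3.818,1
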