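subject,rms_low,rms_high,rms_all
S1,0,0,0
S3,6,0,4.24
S11,11.23,11.23,11.23
S14,0,4.24,3
S15,4.24,0,3
S17,6,12.73,9.95
S19,15.30,4.24,11.22
S21,10.39,10.39,10.39
S22,7.35,10.39,8.49
S24,0,4.24,3
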