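id,group,main_weight,polarity,weight,rank
S11,S1,0.3341,negative,0.1176,4
S12,S1,0.3341,negative,0.0994,5
S13,S1,0.3341,positive,0.0343,9
S14,S1,0.3341,positive,0.0408,8
S15,S1,0.3341,positive,0.0205,15
S16,S1,0.3341,negative,0.0207,14
S21,S2,0.3780,negative,0.1185,3
S22,S2,0.3780,negative,0.1233,2
S23,S2,0.3780,positive,0.0304,10
S24,S2,0.3780,positive,0.0410,7
S25,S2,0.3780,positive,0.0111,16
S26,S2,0.3780,negative,0.0090,17
S31,S3,0.2879,positive,0.1836,1
S32,S3,0.2879,positive,0.0739,6
S33,S3,0.2879,positive,0.0301,11
S34,S3,0.2879,positive,0.0230,12
S35,S3,0.2879,negative,0.0227,13
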