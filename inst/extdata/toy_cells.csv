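id,x,y,population
c0_0,0,0,189.01331540606608
c0_1,0,1,349.1929878079056
c0_2,0,2,431.1122905071875
c0_3,0,3,349.1929878079056
c0_4,0,4,189.01331540606608
c1_0,1,0,349.1929878079056
c1_1,1,1,661.1803884299546
c1_2,1,2,820.737402916808
c1_3,1,3,661.1803884299546
c1_4,1,4,349.1929878079056
c2_0,2,0,431.1122905071875
c2_1,2,1,820.737402916808
c2_2,2,2,1020
c2_3,2,3,820.737402916808
c2_4,2,4,431.1122905071875
c3_0,3,0,349.1929878079056
c3_1,3,1,661.1803884299546
c3_2,3,2,820.737402916808
c3_3,3,3,661.1803884299546
c3_4,3,4,349.1929878079056
c4_0,4,0,189.01331540606608
c4_1,4,1,349.1929878079056
c4_2,4,2,431.1122905071875
c4_3,4,3,349.1929878079056
c4_4,4,4,189.01331540606608
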