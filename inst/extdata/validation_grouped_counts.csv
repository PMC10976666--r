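group,label,n,events_any,events_major
1,0-1,218,1,0
2,1.5-2,444,1,1
3,2.5,795,7,5
4,3-4,673,12,10
5,4.5-5,656,7,6
6,5.5-6.5,494,14,11
7,7,200,3,3
8,7.5-8,151,5,5
9,8.5-9.5,157,4,4
10,10-12,58,2,2
11,>=12.5,28,1,1
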