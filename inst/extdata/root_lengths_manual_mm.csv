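image,order_1,order_2,order_3,total_length
1,603,454,186,1242
2,401,395,186,1981
3,227,276,198,1701
4,290,271,303,1864
5,266,295,303,2064
6,181,238,303,2722
7,224,198,303,2825
8,781,2048,873,3746
9,567,2306,752,3942
10,584,2308,749,3954
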