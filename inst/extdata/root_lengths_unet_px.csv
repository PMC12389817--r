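image,order_1,order_2,order_3,total_length
1,1780,380,2345,4505
2,618,149,1390,2157
3,1176,357,2956,4489
4,1849,677,2735,5261
5,2454,922,2825,6201
6,1516,501,2982,4999
7,1322,406,2678,4406
8,2011,578,4476,7171
9,1631,316,4723,6679
10,1945,476,6205,8793
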