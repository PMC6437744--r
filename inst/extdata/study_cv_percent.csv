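subject,pad_1,pad_2,pad_3,pad_4,pad_5,pad_6,pad_7,pad_8,pad_9,pad_10,pad_11,pad_12,pad_13,pad_14,pad_15,pad_16,printed_mean,printed_sd
1,17,20,20,15,13,16,17,10,15,12,18,13,13,15,15,20,15.6,3.0
2,29,20,18,14,17,18,23,23,19,23,16,16,28,14,8,15,18.8,5.4
3,15,26,20,25,27,31,22,12,13,7,28,23,30,21,23,24,21.7,6.8
4,19,16,23,18,17,20,20,17,14,16,17,12,34,11,11,24,18.1,5.7
5,20,30,18,44,29,30,32,28,29,17,17,26,34,22,20,30,26.6,7.3
6,23,25,12,19,23,31,23,20,28,8,28,16,18,44,19,21,22.4,8.2
7,25,19,23,16,23,10,11,13,15,12,9,12,17,12,13,19,15.6,5.1
8,17,14,11,10,12,14,15,11,9,10,13,18,11,15,14,16,13.1,2.7
9,18,19,13,15,14,12,10,14,10,20,21,11,15,11,26,18,15.4,4.5
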