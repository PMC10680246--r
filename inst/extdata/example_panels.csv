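day,fbg,ppg_breakfast,ppg_lunch,ppg_dinner,bg_0300
1,14.2,16.9,17.4,16.8,13.1
2,11.0,13.5,13.9,13.2,10.4
3,8.9,11.2,11.5,10.9,8.2
4,7.6,9.4,9.8,9.5,6.9
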