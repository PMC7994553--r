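group,sample_n,stay,evacuate,inactive,within_county,within_state,out_of_state
shelter_in_place,9953,8493,837,623,552,133,152
stable,16506,13936,1506,1064,1008,220,278
distressed,4187,3338,559,290,381,57,121
abandoned,1960,1320,438,202,343,49,46
all,51020,42277,5322,3421,3624,758,940
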