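scale,intermediate,reclass_high,reclass_low,remaining,expected_events_high,rrr
100000,29445,5434,7229,16782,1082,0.20
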