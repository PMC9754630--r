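# Tokens task, slow post-decision animation (170 ms per remaining token)
schema_version: 1
kind: tokens
speed: slow
Rc: 2
cost: 0.5
Ri: -1
base_iti: 0.5
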