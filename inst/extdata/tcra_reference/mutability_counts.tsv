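base	occurrence	observed
G	2895	77
C	2834	85
A	3498	64
T	3368	57
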