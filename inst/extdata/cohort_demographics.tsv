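characteristic	count
health	5
gastritis	5
duodenum_erosion	1
jejunum_erosion	1
ileum_erosion	3
male	6
female	9
fob_weakly_positive	1
fob_negative	14
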