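from_type	to_type	sequence_change	methylation_variation
IV	I	mutation	unchanged
IV	II	mutation_and_epimutation	hypermethylation
IV	III	ambiguous	unchanged
I	IV	mutation	unchanged
I	II	epimutation	hypermethylation
I	III	mutation_and_epimutation	hypermethylation
II	IV	mutation_and_epimutation	hypomethylation
II	I	epimutation	hypomethylation
II	III	mutation_and_epimutation	unchanged
III	IV	ambiguous	unchanged
III	I	mutation_and_epimutation	hypomethylation
III	II	mutation_and_epimutation	unchanged
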