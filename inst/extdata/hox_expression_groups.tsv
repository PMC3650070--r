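group_name	gene_id
9 hpf WT non-expressed	hoxa4a
9 hpf WT non-expressed	hoxa5a
9 hpf WT non-expressed	hoxa9a
9 hpf WT non-expressed	hoxa11a
9 hpf WT non-expressed	hoxa13a
9 hpf WT non-expressed	hoxa9b
9 hpf WT non-expressed	hoxa11b
9 hpf WT non-expressed	hoxa13b
9 hpf WT non-expressed	hoxb2a
9 hpf WT non-expressed	hoxb4a
9 hpf WT non-expressed	hoxb5a
9 hpf WT non-expressed	hoxb6a
9 hpf WT non-expressed	hoxb9a
9 hpf WT non-expressed	hoxb13a
9 hpf WT non-expressed	hoxb8b
9 hpf WT non-expressed	hoxc1a
9 hpf WT non-expressed	hoxc4a
9 hpf WT non-expressed	hoxc5a
9 hpf WT non-expressed	hoxc6a
9 hpf WT non-expressed	hoxc10a
9 hpf WT non-expressed	hoxc11a
9 hpf WT non-expressed	hoxc12a
9 hpf WT non-expressed	hoxc13a
9 hpf WT non-expressed	hoxc6b
9 hpf WT non-expressed	hoxc12b
9 hpf WT non-expressed	hoxd4a
9 hpf WT non-expressed	hoxd9a
9 hpf WT non-expressed	hoxd10a
9 hpf WT non-expressed	hoxd11a
9 hpf WT non-expressed	hoxd12a
9 hpf WT non-expressed	hoxd13a
9 hf WT expressed	hoxb1a
9 hf WT expressed	hoxb7a
9 hf WT expressed	hoxb5b
9 hf WT expressed	hoxb6b
9 hf WT expressed	hoxc8a
9 hf WT expressed	hoxc9a
6 hpf RA treated uninduced	hoxa9a
6 hpf RA treated uninduced	hoxa11a
6 hpf RA treated uninduced	hoxa13a
6 hpf RA treated uninduced	hoxa9b
6 hpf RA treated uninduced	hoxa11b
6 hpf RA treated uninduced	hoxa13b
6 hpf RA treated uninduced	hoxb2a
6 hpf RA treated uninduced	hoxb4a
6 hpf RA treated uninduced	hoxb6a
6 hpf RA treated uninduced	hoxb7a
6 hpf RA treated uninduced	hoxb9a
6 hpf RA treated uninduced	hoxb13a
6 hpf RA treated uninduced	hoxb8b
6 hpf RA treated uninduced	hoxc6a
6 hpf RA treated uninduced	hoxc8a
6 hpf RA treated uninduced	hoxc9a
6 hpf RA treated uninduced	hoxc10a
6 hpf RA treated uninduced	hoxc11a
6 hpf RA treated uninduced	hoxc12a
6 hpf RA treated uninduced	hoxc13a
6 hpf RA treated uninduced	hoxc6b
6 hpf RA treated uninduced	hoxc12b
6 hpf RA treated uninduced	hoxd4a
6 hpf RA treated uninduced	hoxd9a
6 hpf RA treated uninduced	hoxd10a
6 hpf RA treated uninduced	hoxd11a
6 hpf RA treated uninduced	hoxd12a
6 hpf RA treated uninduced	hoxd13a
6 hpf RA treated induced	hoxa4a
6 hpf RA treated induced	hoxa5a
6 hpf RA treated induced	hoxb1a
6 hpf RA treated induced	hoxb5a
6 hpf RA treated induced	hoxb5b
6 hpf RA treated induced	hoxb6b
6 hpf RA treated induced	hoxc1a
6 hpf RA treated induced	hoxc4a
6 hpf RA treated induced	hoxc5a
RA-only	hoxa4a
RA-only	hoxa5a
RA-only	hoxb5a
RA-only	hoxc1a
RA-only	hoxc4a
RA-only	hoxc5a
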