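# Example study configuration (key: value pairs; commas make vectors)
seed: 11
n_per_group: 8
n_fdt: 6
n_perm: 100
models: RW, HGF2, HGF3
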