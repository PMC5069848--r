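# Weak neutral genetic structure, no trait divergence, reduced within-group
# variance (stabilizing selection regime)
name: stabilizing
group_sizes: [83, 217, 71]
n_loci: 18
alleles_per_locus: [3, 25]
target_fst: 0.005
depth_per_group: [40, 80, 120]
missing_rate: 0.02
trait_profile: stabilizing
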