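# Example cohort configuration for run_pipeline() / the osteovox CLI.
# Scaled-down sizes; the full study conditions use n: 100, length: 400,
# domain_edge: 500.
cohorts:
  - kind: cylinder
    n: 5
    seed: 1
    aspect_ratio: 1.5
    length: 120
    domain_edge: 160
  - kind: ellipsoid
    n: 5
    seed: 101
    voxel_size: 0.8
    alignment: woven
  - kind: ellipsoid
    n: 5
    seed: 201
    voxel_size: 0.8
    alignment: parallel_fibred
supersampling: 5
binarise: midpoint
write_stacks: false
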