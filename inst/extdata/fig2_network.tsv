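# Worked-example network: 8 nodes, 8 edges, capacities C=(1,2,2,2,1,2,2,1).
# Synthetic transcription validated by validate_fig2().
source	target	capacity
v1	v7	1
v5	v3	2
v7	v5	2
v3	v4	2
v1	v8	1
v1	v3	2
v5	v6	2
v6	v2	1
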