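{"haplogroups":[{"sample_id":"F001","group":"F","haplogroup":"L3"},{"sample_id":"F002","group":"F","haplogroup":"L3"},{"sample_id":"F003","group":"F","haplogroup":"L1"},{"sample_id":"F004","group":"F","haplogroup":"L2"},{"sample_id":"F005","group":"F","haplogroup":"L3"},{"sample_id":"F006","group":"F","haplogroup":"L1"},{"sample_id":"NF001","group":"NF","haplogroup":"L3"},{"sample_id":"NF002","group":"NF","haplogroup":"L1"},{"sample_id":"NF003","group":"NF","haplogroup":"L1"},{"sample_id":"NF004","group":"NF","haplogroup":"L1"},{"sample_id":"NF005","group":"NF","haplogroup":"L1"},{"sample_id":"NF006","group":"NF","haplogroup":"L3"},{"sample_id":"NF007","group":"NF","haplogroup":"L1"},{"sample_id":"NF008","group":"NF","haplogroup":"L1"},{"sample_id":"NF009","group":"NF","haplogroup":"L1"},{"sample_id":"NF010","group":"NF","haplogroup":"L1"}],"planted":[{"position":400,"allele":"A","p_F":0.1,"p_NF":0.8,"n_carriers_F":1,"n_carriers_NF":6}],"heteroplasmies":[{"sample_id":"NF003","position":262,"bases":"A/C"}],"homopolymer_indels":[{"sample_id":"F002","position":17},{"sample_id":"F003","position":17},{"sample_id":"F006","position":14},{"sample_id":"NF001","position":19},{"sample_id":"NF003","position":16}],"tract":{"start":12,"end":19},"seed":2026}
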