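gene_id	rank
g0001	5
g0002	6
g0003	3
g0004	1
g0005	5
g0006	5
g0007	5
g0008	5
g0009	6
g0010	4
g0011	6
g0012	4
g0013	3
g0014	4
g0015	5
g0016	4
g0017	3
g0018	5
g0019	2
g0020	5
g0021	4
g0022	2
g0023	2
g0024	5
g0025	6
g0026	4
g0027	5
g0028	3
g0029	1
g0030	5
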