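gene_id	stage1	stage2	stage3	stage4	stage5
g0001	339.272	315.652	440.655	355.761	424.601
g0002	191.952	178.865	249.546	201.143	236.254
g0003	370.294	345.166	481.244	388.403	456.171
g0004	466.585	434.723	606.49	489.349	574.952
g0005	323.532	305.349	426.247	344.139	404.275
g0006	458.659	420.711	587.166	473.956	557.107
g0007	366.333	346.963	484.037	390.93	459.287
g0008	248.474	225.798	315.265	254.434	299.194
g0009	268.309	250.111	348.89	281.413	330.539
g0010	211.121	196.802	274.508	221.562	259.97
g0011	328.042	305.667	426.055	343.845	403.874
g0012	314.487	292.588	408.387	336.241	394.973
g0013	216.953	202.292	282.07	227.583	267.334
g0014	355.434	330.967	461.642	367.64	431.857
g0015	371.417	345.725	482.375	389.504	449.139
g0016	356.346	331.852	463.13	367.227	431.718
g0017	268.331	250.015	348.825	281.206	330.56
g0018	188.303	168.887	235.545	190.268	223.55
g0019	186.965	174.369	242.889	196.112	230.147
g0020	213.551	198.835	277.304	224.116	270.231
g0021	227.52	211.724	295.671	245.787	289.052
g0022	181.64	168.979	228.986	184.898	217.233
g0023	413.506	384.42	545.733	440.737	517.721
g0024	341.149	317.347	443.105	357.849	412.184
g0025	398.106	370.833	517.393	417.454	490.611
g0026	265.782	247.595	345.563	278.832	327.502
g0027	158.44	147.242	205.561	166.125	200.175
g0028	411.081	382.861	534.11	430.876	506.349
g0029	156.731	146.195	203.844	164.331	193.189
g0030	219.245	208.658	291.142	234.926	276.136
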