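# Curated per-gene summary of the published BBX families of the two orchid
# genomes (Dendrobium officinale, Phalaenopsis equestris): scaffold location,
# theoretical isoelectric point (pI) and molecular weight (Da).
gene_id	genome	scaffold	start	end	pi	mw
DoBBX01	Do	scaffold1023	110887	111429	5.78	19334.08
DoBBX02	Do	scaffold1579	145245	147705	8.4	16408.94
DoBBX03	Do	scaffold1615	111626	113154	6.62	49069.17
DoBBX04	Do	scaffold2703	47629	52112	8.05	23160.00
DoBBX05	Do	scaffold3036	22448	37134	6.38	61659.92
DoBBX06	Do	scaffold3055	36993	49949	5.97	47501.90
DoBBX07	Do	scaffold4316	51281	52020	6.58	22581.62
DoBBX08	Do	scaffold476	4575	5695	5.17	31455.23
DoBBX10	Do	scaffold5567	27303	27881	5.89	42498.73
DoBBX09	Do	scaffold5567	17687	22526	4.8	40018.87
DoBBX11	Do	scaffold5786	5947	12621	5.74	21072.85
DoBBX12	Do	scaffold6558	50428	52902	5.9	49066.97
DoBBX13	Do	scaffold7094	5715	11039	4.76	29329.54
DoBBX14	Do	scaffold7130	45763	46503	6.49	14648.51
DoBBX15	Do	scaffold1079	550	4814	4.74	15960.99
DoBBX16	Do	scaffold11444	5072	6516	5.61	32830.90
DoBBX17	Do	scaffold11472	11595	16499	7.48	33074.70
DoBBX18	Do	scaffold11757	21929	22994	6.06	30682.53
DoBBX19	Do	scaffold15694	2698	3306	5.06	22740.86
PeBBX01	Pe	Scaffold000002	12666119	12668574	6.02	35945.50
PeBBX02	Pe	Scaffold000002	14834552	14844365	5.74	39882.90
PeBBX03	Pe	Scaffold000008	219001	219795	5.13	29606.44
PeBBX04	Pe	Scaffold000028	40165	74304	6.65	23352.53
PeBBX05	Pe	Scaffold000202	1196612	1197568	8.61	35776.22
PeBBX06	Pe	Scaffold000219	340992	368429	6.83	49942.19
PeBBX07	Pe	Scaffold000224	4007418	4008506	6.02	37255.94
PeBBX08	Pe	Scaffold000297	942007	946699	5.5	37633.50
PeBBX09	Pe	Scaffold000411	691452	710139	6.85	47215.68
PeBBX10	Pe	Scaffold000413	746717	747431	7.93	21747.15
PeBBX11	Pe	Scaffold000584	11714	12343	4.35	23138.88
PeBBX12	Pe	Scaffold001081	902228	902798	6.57	18004.64
PeBBX13	Pe	Scaffold001148	10708	12869	5.65	26279.96
PeBBX14	Pe	Scaffold1976	2433	3242	6.68	7492.76
PeBBX15	Pe	Scaffold21087	95748	102447	5.76	20454.13
PeBBX16	Pe	Scaffold23386	116085	131657	5.53	45564.70
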