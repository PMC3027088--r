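chrom	pos	marker_id	maf	stage1_p	snp_effect	snp_se	stage2_p
3	59877841	rs1825630	0.444	3.70e-5	9.46	2.11	7.99e-6
7	65255030	rs875971	0.324	3.99e-5	10.69	2.24	4.09e-6
7	65668047	rs801193	0.337	3.97e-5	11.13	2.23	3.65e-6
7	65700370	rs10258739	0.318	2.11e-5	10.64	2.26	2.50e-6
7	65733463	AFFX_9317457	0.332	6.24e-6	11.25	2.23	6.20e-7
7	65733463	rs10263935	0.324	9.06e-6	11.42	2.28	4.26e-7
7	65790536	rs2659915	0.334	4.10e-5	10.84	2.22	4.27e-6
8	117625451	rs4876662	0.195	2.70e-5	13.17	2.58	2.23e-6
16	57316833	rs12600277	0.162	2.84e-5	13.99	2.98	2.72e-6
20	1888504	rs6045666	0.351	3.21e-5	12.58	2.26	2.97e-6
20	1889171	rs6045676	0.356	5.31e-7	11.47	2.28	3.28e-8
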