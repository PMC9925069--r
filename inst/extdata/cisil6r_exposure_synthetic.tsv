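SNP	CHR	POS	EA	OA	EAF	BETA	SE	P	N
rs6868725	1	154131721	T	C	0.17	0.0736	0.0058	6.75e-37	522681
rs2723237	1	154132993	A	C	0.378	0.0363	0.005	3.87e-13	522681
rs8739341	1	154141039	G	A	0.131	0.0886	0.0083	1.34e-26	522681
rs8878958	1	154170094	A	C	0.158	0.0853	0.0051	8.55e-63	522681
rs8281104	1	154172908	G	A	0.423	-0.0745	0.0072	4.31e-25	522681
rs5894215	1	154206464	C	T	0.373	-0.0215	0.0036	2.34e-09	522681
rs5490505	1	154215929	A	G	0.142	0.044	0.003	1.05e-48	522681
rs8132750	1	154231545	A	G	0.116	-0.0436	0.0038	1.79e-30	522681
rs8957083	1	154253446	A	C	0.158	-0.0638	0.008	1.52e-15	522681
rs7213942	1	154341159	A	G	0.067	-0.0326	0.0031	7.28e-26	522681
rs9500533	1	154372366	G	A	0.409	0.0225	0.0038	3.2e-09	522681
rs2598388	1	154374989	T	C	0.248	-0.0284	0.0047	1.52e-09	522681
rs1413645	1	154377706	G	A	0.25	-0.0598	0.0074	6.42e-16	522681
rs0172220	1	154419691	T	C	0.303	0.0534	0.0057	7.36e-21	522681
rs2228145	1	154426970	C	A	0.39	-0.0558	0.01	2.41e-08	522681
rs6951196	1	154439370	T	C	0.424	0.0479	0.0081	3.35e-09	522681
rs6464617	1	154447705	A	C	0.24	0.0511	0.0053	5.34e-22	522681
rs0232147	1	154459073	A	G	0.27	-0.0718	0.0086	6.89e-17	522681
rs0206724	1	154499324	G	T	0.12	-0.0519	0.0064	5.09e-16	522681
rs2126335	1	154508582	A	G	0.261	0.0808	0.0059	1.09e-42	522681
rs0935711	1	154533241	G	A	0.343	0.069	0.0071	2.52e-22	522681
rs5397788	1	154590865	C	T	0.324	-0.0699	0.0049	3.6e-46	522681
rs9936563	1	154607994	G	T	0.094	0.031	0.0026	8.97e-33	522681
rs7312643	1	154616962	T	C	0.155	-0.0545	0.0041	2.55e-40	522681
rs4187261	1	154661724	A	G	0.22	0.082	0.0048	1.98e-65	522681
rs3118622	1	154681712	G	A	0.146	0.0803	0.0088	7.17e-20	522681
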