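hgvs_p	hdr_score	hdr_upper_ci	ps3	pm1	pm5	pp1	pm3_bp2	pp3_bp4	freq	before_class	final_class	note
p.Ala2603Pro	1.07	1.25	PS3	-	-	-	-	-	-	N/O	N/O	
p.Ala2730Pro	1.01	1.15	PS3	PM1_supp	-	PP1	-	inc	-	VUS	LP	
p.Ala2780Asp	1.04	1.21	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Ala2786Pro	1.22	1.43	PS3	-	-	-	-	-	-	N/O	N/O	
p.Ala3028Pro	1.18	1.38	PS3	PM1	-	PP1_mod	PM3	BP4	PM2_supp	LP	P	
p.Ala3122Pro	1.09	1.24	PS3	-	-	-	-	-	-	N/O	N/O	
p.Asp2723Ala	0.99	1.15	PS3	PM1	PM5	PP1	-	PP3	PM2_supp	LP	P	
p.Asp2723Gly	0.94	1.10	PS3	-	PM5	-	-	PP3	PM2_supp	VUS	P	
p.Asp2723His	1.00	1.07	PS3	-	-	-	-	PP3	PM2_supp	VUS	P	
p.Asp2723Asn	0.89	1.04	PS3	PM1	-	-	-	inc	PM2_supp	VUS	LP	
p.Asp2723Val	0.98	1.11	PS3	PM1	PM5	PP1	-	PP3	PM2_supp	LP	P	
p.Asp2723Tyr	1.17	1.36	PS3	-	-	-	-	-	-	N/O	N/O	
p.Asp2819His	1.37	1.60	PS3	-	-	-	-	-	-	N/O	N/O	
p.Asp2819Val	1.20	1.36	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Asp3073Gly	1.08	1.26	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Asp3073Tyr	0.98	1.15	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Asp3095Glu	0.95	1.07	PS3	PM1	-	-	-	inc	PM2_supp	VUS	P	
p.Asp3095Gly	1.04	1.21	PS3	-	PM5	PP1	-	inc	PM2_supp	VUS	P	
p.Glu2599Gly	1.46	1.66	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Glu2663Lys	0.83	0.93	PS3	PM1	-	PP1	-	inc	PM2_supp	VUS	P	
p.Phe2562Cys	1.32	1.54	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Phe2562Val	1.08	1.26	PS3	-	-	-	-	-	-	N/O	N/O	
p.Phe2642Ser	1.07	1.25	PS3	-	-	-	-	-	-	N/O	N/O	
p.Phe3146Ser	1.06	1.23	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Gly2508Arg	1.08	1.26	PS3	-	-	-	-	-	-	N/O	N/O	
p.Gly2596Glu	1.12	1.30	PS3	-	-	-	-	PP3	PM2_supp	VUS	LP	
p.Gly2596Arg	1.28	1.49	PS3	-	-	-	-	PP3	PM2_supp	VUS	LP	
p.Gly2609Val	1.07	1.25	PS3	PM1_supp	-	-	-	inc	PM2_supp	VUS	LP	
p.Gly2724Val	1.07	1.24	PS3	-	-	-	-	PP3	PM2_supp	VUS	LP	
p.Gly2724Trp	1.12	1.27	PS3	-	-	-	-	-	-	N/O	N/O	
p.Gly2748Asp	0.95	1.08	PS3	-	-	PP1	-	PP3	-	VUS	LP	
p.Gly2748Ser	0.97	1.13	PS3	-	-	-	-	-	-	N/O	N/O	
p.Gly2793Glu	1.19	1.23	PS3	PM1	-	-	-	PP3	PM2_supp	VUS	LP	
p.Gly2793Arg	1.18	1.37	PS3	PM1_supp	PM5	-	-	PP3	-	VUS	P	
p.Gly2793Val	1.16	1.32	PS3	-	PM5	-	-	PP3	PM2_supp	VUS	P	
p.Gly3003Glu	1.35	1.57	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Gly3076Glu	1.04	1.18	PS3	PM1	-	-	-	PP3	PM2_supp	VUS	P	
p.Gly3076Arg	1.03	1.21	PS3	-	-	-	-	-	-	N/O	N/O	
p.Gly3076Val	1.16	1.30	PS3	PM1	PM5	-	-	inc	PM2_supp	LP	P	
p.His2623Arg	0.83	0.92	PS3	PM1	-	PP1	-	PP3	PM2_supp	LP	P	
p.His2623Tyr	1.15	1.35	PS3	-	PM5	-	-	inc	PM2_supp	VUS	LP	
p.Ile2627Phe	1.01	1.18	PS3	-	-	-	-	inc	PM2_supp	VUS	LP	
p.Ile2627Asn	1.16	1.32	PS3	-	PM5	-	-	inc	PM2_supp	VUS	LP	
p.Ile2751Ser	1.04	1.21	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Lys2630Gln	0.98	1.15	PS3	-	-	-	-	-	-	N/O	N/O	
p.Lys2657Thr	1.05	1.19	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Leu2510Pro	1.06	1.24	PS3	PM1_supp	-	-	PM3_st	PP3	PM2_supp	LP	P	
p.Leu2604Pro	0.98	1.14	PS3	PM1	-	-	-	PP3	PM2_supp	VUS	P	
p.Leu2647Pro	1.00	1.13	PS3	-	-	PP1_mod	-	PP3	PM2_supp	VUS	P	
p.Leu2653Pro	0.92	1.07	PS3	-	-	-	-	inc	PM2_supp	VUS	LP	
p.Leu2656Pro	1.12	1.31	PS3	-	-	-	-	-	-	N/O	N/O	
p.Leu2686Pro	0.86	0.97	PS3	PM1	-	-	PM3_st	inc	PM2_supp	LP	P	
p.Leu2688Pro	1.00	1.13	PS3	-	-	PP1_mod	-	PP3	PM2_supp	VUS	P	
p.Leu2721His	0.92	1.07	PS3	PM1	-	-	-	inc	PM2_supp	VUS	LP	
p.Leu2753Pro	1.01	1.11	PS3	-	-	-	-	BP4	PM2_supp	VUS	VUS	
p.Leu2792Arg	1.07	1.24	PS3	-	-	-	-	PP3	PM2_supp	VUS	LP	
p.Leu3101Arg	1.15	1.30	PS3	PM1	-	PP1	PM3_st	inc	PM2_supp	P	P	
p.Leu3125Phe	1.08	1.26	PS3	-	-	-	-	-	-	N/O	N/O	
p.Leu3125His	0.96	1.12	PS3	-	-	-	-	-	-	N/O	N/O	
p.Leu3125Arg	0.91	1.06	PS3	-	-	-	-	-	-	N/O	N/O	
p.Leu3180Pro	1.37	1.59	PS3	-	-	-	-	-	-	N/O	N/O	
p.Asn2622Asp	1.20	1.36	PS3	-	-	-	-	-	-	N/O	N/O	
p.Asn2622Ser	1.40	1.56	PS3	-	-	-	-	inc	BS1	VUS	VUS	0.020% AFR
p.Asn2781Ile	1.02	1.15	PS3	PM1_supp	-	-	-	inc	PM2_supp	VUS	LP	
p.Asn3124Ile	0.99	1.11	PS3	PM1	-	-	-	inc	PM2_supp	VUS	P	
p.Gln2561Pro	1.13	1.26	PS3	-	-	-	-	-	-	N/O	N/O	
p.Arg2625Ile	1.17	1.37	PS3	-	-	-	-	-	-	N/O	N/O	
p.Arg2784Trp	1.35	1.57	PS3	PM1_supp	-	PP1	PM3	inc	-	VUS	P	
p.Arg2824Thr	1.36	1.58	PS3	-	-	-	-	-	-	N/O	N/O	
p.Arg3052Leu	1.04	1.21	PS3	-	PM5	-	-	inc	PM2_supp	VUS	LP	
p.Arg3052Trp	0.97	1.08	PS3	-	-	-	-	inc	-	VUS	P	
p.Ser2691Tyr	1.37	1.60	PS3	-	-	-	-	-	-	N/O	N/O	
p.Thr2722Ala	1.39	1.62	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Thr2722Ile	1.24	1.44	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
p.Thr2722Lys	1.00	1.16	PS3	PM1	PM5	-	-	inc	PM2_supp	LP	P	
p.Thr2722Arg	1.08	1.26	PS3	PM1	-	-	-	inc	PM2_supp	VUS	P	
p.Val2652Gly	1.14	1.33	PS3	-	-	-	-	-	-	N/O	N/O	
p.Val2687Phe	1.14	1.29	PS3	PM1	-	-	-	inc	PM2_supp	VUS	LP	
p.Trp2619Cys	1.00	1.14	PS3	-	-	-	-	PP3	PM2_supp	VUS	LP	
p.Trp2619Gly	1.04	1.18	PS3	PM1	-	-	-	PP3	PM2_supp	VUS	P	
p.Trp2619Ser	0.97	1.13	PS3	-	-	-	-	-	-	N/O	N/O	
p.Trp2626Arg	1.09	1.23	PS3	PM1	-	-	-	PP3	PM2_supp	VUS	P	
p.Trp2725Leu	1.35	1.58	PS3	-	-	-	-	-	-	N/O	N/O	
p.Trp2788Arg	1.05	1.23	PS3	PM1_supp	-	-	-	inc	PM2_supp	VUS	LP	
p.Trp2788Ser	1.09	1.21	PS3	-	PM5	-	-	inc	PM2_supp	VUS	LP	
p.Tyr2624Cys	1.51	1.64	PS3	PM1_supp	-	-	-	PP3	PM2_supp	VUS	LP	
p.Tyr2624His	1.02	1.19	PS3	-	-	-	-	-	-	N/O	N/O	
p.Tyr2660Asp	1.17	1.30	PS3	-	-	-	-	-	-	N/O	N/O	
p.Tyr2726Cys	1.36	1.54	PS3	PM1	-	-	-	PP3	PM2_supp	VUS	P	
p.Tyr3006Asp	1.06	1.18	PS3	-	-	-	-	inc	PM2_supp	VUS	VUS	
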