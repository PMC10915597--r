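model_name	model_type	lnL	k	delta_aic	weight
VI	Migrations and divergence	-6273.820533	13	0	1
VII	Migrations, divergence, and expansion	-6274.55217	15	5.463274405	0.0651126
III	Migrations and divergence	-6274.999944	16	8.358821986	0.015307521
V	Migrations and divergence	-6277.374519	15	11.10797085	0.003871995
II	Migrations and divergence	-6282.69762	15	21.75417302	1.89E-05
IV	Migrations and divergence	-6288.002384	14	30.3637023	2.55E-07
XI	Migrations, divergence, and expansion	-6286.667405	16	31.69374272	1.31E-07
VIII	Migrations, divergence, and expansion	-6307.841439	12	66.04181228	4.56E-15
XII	Migrations, divergence, expansion, and bottlenecks	-6340.19633	16	138.7515946	7.42E-31
IX	Migrations, divergence, and expansion	-6354.465715	12	159.290364	2.57E-35
X	Migrations, divergence, and expansion	-6354.835164	12	160.0292625	1.78E-35
I	Migrations and divergence	-6374.94489	5	186.248714	3.60E-41
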