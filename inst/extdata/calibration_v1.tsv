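# dvos synthetic-cohort calibration table, version 1
# Cohort summary statistics (mean, sd) and categorical proportions by group for
# a diabetic cohort of 118 PAD and 118 non-PAD subjects.
# Units: delta_hbo umol/L; hf umol/L per 5-s interval; vo2 mL O2/100 mL tissue/min;
# tp s; age years; bmi kg/m2; dm_duration years; htn_duration years; abi ratio.
# For proportions (table = proportions) `mean` is the proportion and sd is NA.
table	group	pressure	parameter	mean	sd
features	nonPAD	60	delta_hbo	6.81	4.11
features	nonPAD	60	hf	2.48	0.85
features	nonPAD	60	vo2	0.066	0.035
features	nonPAD	60	tp	23.44	9.04
features	PAD	60	delta_hbo	2.01	1.74
features	PAD	60	hf	0.86	0.49
features	PAD	60	vo2	0.040	0.022
features	PAD	60	tp	20.70	9.54
features	nonPAD	100	delta_hbo	9.44	5.93
features	nonPAD	100	hf	2.90	1.33
features	nonPAD	100	vo2	0.079	0.050
features	nonPAD	100	tp	20.86	7.09
features	PAD	100	delta_hbo	3.90	3.55
features	PAD	100	hf	1.35	0.90
features	PAD	100	vo2	0.052	0.029
features	PAD	100	tp	17.12	4.98
covariates	nonPAD	NA	age	54.8	13.7
covariates	PAD	NA	age	59.1	7.9
covariates	nonPAD	NA	bmi	30.3	5.9
covariates	PAD	NA	bmi	31.7	5.5
covariates	nonPAD	NA	dm_duration	10.8	9.5
covariates	PAD	NA	dm_duration	13.5	8.4
covariates	nonPAD	NA	htn_duration	5.4	6.9
covariates	PAD	NA	htn_duration	8.0	8.5
covariates	nonPAD	NA	abi_left	1.09	0.08
covariates	PAD	NA	abi_left	0.88	0.14
covariates	nonPAD	NA	abi_right	1.10	0.07
covariates	PAD	NA	abi_right	0.92	0.11
proportions	nonPAD	NA	male	0.44	NA
proportions	PAD	NA	male	0.42	NA
proportions	nonPAD	NA	smoking	0.30	NA
proportions	PAD	NA	smoking	0.19	NA
proportions	nonPAD	NA	statin	0.59	NA
proportions	PAD	NA	statin	0.64	NA
proportions	nonPAD	NA	antiplatelet	0.68	NA
proportions	PAD	NA	antiplatelet	0.89	NA
proportions	nonPAD	NA	antihypertensive	0.55	NA
proportions	PAD	NA	antihypertensive	0.71	NA
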