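patient,age,sex,side,pass_1_5,pass_1_8,eac_touched,eac_thinning_required,planned_dist_eac_mm,d_fn_mm,d_ct_mm,m_fn_1_5_mm,m_ct_1_5_mm,jig_deviation_mm,bone_thickness_mm
01,69,F,L,yes,yes,no,yes,0.6,1.04,1.61,0.29,0.86,0.14,6.9
02,61,F,L,yes,yes,no,no,0.7,1.16,1.29,0.41,0.54,0.24,4.6
03,53,F,L,yes,no,no,no,1.9,1.06,2.28,0.31,1.53,0.08,5.6
04,32,M,L,yes,yes,no,no,1.8,1.33,1.08,0.58,0.33,0.08,4.8
05,60,F,R,yes,no,no,no,0.9,1.08,1.60,0.33,0.85,0.16,6.2
06,72,M,R,yes,no,no,no,1.3,1.11,0.95,0.36,0.20,0.05,3.7
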