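symbol	direction	probesets	pTxActive	pTxInactive
NFKBIA	up	NFKBIA_s1_at,NFKBIA_s2_at	NA	NA
TNFAIP3	up	TNFAIP3_s1_at,TNFAIP3_s2_at	NA	NA
BIRC3	up	BIRC3_s1_at,BIRC3_s2_at	NA	NA
CCL2	up	CCL2_s1_at,CCL2_s2_at	NA	NA
CXCL8	up	CXCL8_s1_at,CXCL8_s2_at	NA	NA
ICAM1	up	ICAM1_s1_at,ICAM1_s2_at	NA	NA
IL6	up	IL6_s1_at,IL6_s2_at	NA	NA
TNF	up	TNF_s1_at,TNF_s2_at	NA	NA
TRAF1	up	TRAF1_s1_at	NA	NA
BCL2A1	up	BCL2A1_s1_at	NA	NA
BCL2L1	up	BCL2L1_s1_at	NA	NA
PLAU	up	PLAU_s1_at	NA	NA
PTGS2	up	PTGS2_s1_at	NA	NA
VCAM1	up	VCAM1_s1_at	NA	NA
SOD2	up	SOD2_s1_at	NA	NA
CD40	up	CD40_s1_at	NA	NA
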