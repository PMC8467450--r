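!Series_title	"synthetic example series (not a GEO deposit)"
!Series_platform_id	"GPL570-like synthetic"
!Sample_title	"sample A"	"sample B"	"sample C"
!Sample_geo_accession	"SYN001"	"SYN002"	"SYN003"
!series_matrix_table_begin
"ID_REF"	"SYN001"	"SYN002"	"SYN003"
"NFKBIA_s1_at"	7.91	5.02	8.12
"NFKBIA_s2_at"	8.05	4.88	7.96
"TNFAIP3_s1_at"	7.66	5.31	8.40
"BCL2A1_f1_at"	6.12	5.95	7.84
!series_matrix_table_end
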