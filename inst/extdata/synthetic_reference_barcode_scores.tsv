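group_id	genotype_class	n_cells	mean_score
stop_gained_01	stop_gained	8	0.85
stop_gained_02	stop_gained	12	0.86
stop_gained_03	stop_gained	15	0.87
stop_gained_04	stop_gained	22	0.88
stop_gained_05	stop_gained	9	0.89
stop_gained_06	stop_gained	30	0.9
stop_gained_07	stop_gained	11	0.91
stop_gained_08	stop_gained	8	0.92
stop_gained_09	stop_gained	12	0.93
stop_gained_10	stop_gained	15	0.94
stop_gained_11	stop_gained	22	0.95
stop_gained_12	stop_gained	9	0.96
splice_01	splice	30	0.86
splice_02	splice	11	0.867
splice_03	splice	8	0.874
splice_04	splice	12	0.881
splice_05	splice	15	0.888
splice_06	splice	22	0.895
splice_07	splice	9	0.902
splice_08	splice	30	0.908
splice_09	splice	11	0.915
splice_10	splice	8	0.922
splice_11	splice	12	0.929
splice_12	splice	15	0.936
splice_13	splice	22	0.943
splice_14	splice	9	0.95
splice_15	splice	30	0.1
WT_01	WT	11	0.03
WT_02	WT	8	0.032
WT_03	WT	12	0.033
WT_04	WT	15	0.035
WT_05	WT	22	0.037
WT_06	WT	9	0.038
WT_07	WT	30	0.04
WT_08	WT	11	0.042
WT_09	WT	8	0.043
WT_10	WT	12	0.045
WT_11	WT	15	0.047
WT_12	WT	22	0.049
WT_13	WT	9	0.05
WT_14	WT	30	0.052
WT_15	WT	11	0.054
WT_16	WT	8	0.055
WT_17	WT	12	0.057
WT_18	WT	15	0.059
WT_19	WT	22	0.06
WT_20	WT	9	0.062
WT_21	WT	30	0.064
WT_22	WT	11	0.065
WT_23	WT	8	0.067
WT_24	WT	12	0.069
WT_25	WT	15	0.07
WT_26	WT	22	0.072
WT_27	WT	9	0.074
WT_28	WT	30	0.076
WT_29	WT	11	0.077
WT_30	WT	8	0.079
WT_31	WT	12	0.081
WT_32	WT	15	0.082
WT_33	WT	22	0.084
WT_34	WT	9	0.086
WT_35	WT	30	0.087
WT_36	WT	11	0.089
WT_37	WT	8	0.091
WT_38	WT	12	0.092
WT_39	WT	15	0.094
WT_40	WT	22	0.096
WT_41	WT	9	0.097
WT_42	WT	30	0.099
WT_43	WT	11	0.101
WT_44	WT	8	0.102
WT_45	WT	12	0.104
WT_46	WT	15	0.106
WT_47	WT	22	0.108
WT_48	WT	9	0.109
WT_49	WT	30	0.111
WT_50	WT	11	0.113
WT_51	WT	8	0.114
WT_52	WT	12	0.116
WT_53	WT	15	0.118
WT_54	WT	22	0.119
WT_55	WT	9	0.121
WT_56	WT	30	0.123
WT_57	WT	11	0.124
WT_58	WT	8	0.126
WT_59	WT	12	0.128
WT_60	WT	15	0.129
WT_61	WT	22	0.131
WT_62	WT	9	0.133
WT_63	WT	30	0.135
WT_64	WT	11	0.136
WT_65	WT	8	0.138
WT_66	WT	12	0.14
WT_67	WT	15	0.141
WT_68	WT	22	0.143
WT_69	WT	9	0.145
WT_70	WT	30	0.146
WT_71	WT	11	0.148
WT_72	WT	8	0.15
WT_73	WT	12	0.15
WT_74	WT	15	0.15
WT_75	WT	22	0.15
WT_76	WT	9	0.15
WT_77	WT	30	0.9
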