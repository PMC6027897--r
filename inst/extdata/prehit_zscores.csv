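compound_id,substance,z_rep1,z_rep2,z_rep3,retest_phase1,retest_phase2,retest_phase3,retest_phase4
W01,CRUSTECDYSONE,3.36,2.24,3.03,rescued_delay_100uM,size_trend,size_trend,positive
W02,TETRACYCLINE HUDROCHLORIDE,2.84,1.01,2.39,z_gt2_3x_50uM,size_trend,negative,negative
W03,HARMINE,3.37,1.92,2.41,z_gt2_multi,size_trend,negative,negative
W04,SULFLURAMID,4.45,6.22,-0.01,z_gt2_3x_12.5uM,apparent_only,negative,not_tested
W05,URSOCHOLANIC ACID,8.61,7.51,1.85,insoluble_25_50uM,apparent_only,negative,not_tested
W06,5a-ANDROSTANE,6.46,-1.10,2.44,z_gt2_multi,negative,not_tested,not_tested
W07,IRIGENIN TRIMETHYLETHER,0.73,5.62,4.90,z_gt2_multi,negative,not_tested,not_tested
W08,PATULIN,-0.43,2.22,2.63,z_gt2_multi,negative,not_tested,not_tested
W09,ANTIMONY POTASSIUM TARTRATE TRIHYDRATE,2.30,0.57,2.66,z_gt2_multi,negative,not_tested,not_tested
W10,ALOGLIPTIN BENZOATE,2.23,8.26,-2.26,z_gt2_multi,negative,not_tested,not_tested
W11,CEFEPIME HYDROCHLORIDE,3.25,-0.12,3.85,z_gt2_2x_50uM,negative,not_tested,not_tested
W12,PALMIDROL (5mM),3.95,1.01,5.46,no_rescue_10uM_21C,not_tested,not_tested,not_tested
W13,"THIOGUANINE, TIOGUANINE",3.51,-0.91,0.80,z_not_gt2_multi,not_tested,not_tested,not_tested
W14,"THIOGUANINE, TIOGUANINE",0.91,-0.02,4.97,z_not_gt2_multi,not_tested,not_tested,not_tested
W15,CAPTAN,4.11,-3.41,3.36,z_not_gt2_multi,not_tested,not_tested,not_tested
W16,AGARIC ACID,3.16,1.90,4.05,z_not_gt2_multi,not_tested,not_tested,not_tested
W17,ZONISAMIDE,0.42,3.19,2.55,z_not_gt2_multi,not_tested,not_tested,not_tested
W18,BROXALDINE,2.05,-1.05,6.62,z_not_gt2_multi,not_tested,not_tested,not_tested
W19,PICEID,2.66,3.04,2.06,not_tested,not_tested,not_tested,not_tested
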