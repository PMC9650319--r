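synthetic_pathway_01	synthetic set	lip_068	pol_027	lip_129	pol_022	lip_043	lip_014
synthetic_pathway_02	synthetic set	pol_047	lip_051	lip_085	lip_021	lip_106	pol_042	lip_074	lip_007	lip_073	lip_079
synthetic_pathway_03	synthetic set	lip_037	lip_105	lip_110	pol_025	lip_034	lip_106	lip_126	lip_089	pol_032	pol_067	lip_033	lip_084	pol_023	lip_070	lip_074	lip_042	pol_026	lip_111	pol_008	pol_016	lip_020	lip_044	lip_121	lip_087	pol_064	pol_055	lip_040	pol_069
synthetic_pathway_04	synthetic set	lip_119	pol_058	lip_122	lip_039	pol_039	lip_042
synthetic_pathway_05	synthetic set	lip_045	pol_006	lip_022	pol_066	pol_053	lip_115	lip_104	lip_070	pol_070	pol_071
synthetic_pathway_06	synthetic set	pol_069	lip_013	lip_040	pol_036	lip_089	lip_023	lip_110	lip_084	lip_103	lip_029	pol_001	pol_010	pol_016	lip_108	lip_048
synthetic_pathway_07	synthetic set	lip_045	pol_009	lip_031	lip_102	pol_005	lip_073
synthetic_pathway_08	synthetic set	lip_118	lip_090	lip_048	lip_107	lip_064	lip_103	lip_060	lip_051	lip_034	lip_138	lip_129	lip_043	pol_047	lip_026	pol_003
synthetic_pathway_09	synthetic set	lip_029	pol_012	pol_030	lip_048	pol_064	lip_039	lip_024	pol_041	lip_040	lip_083
synthetic_pathway_10	synthetic set	pol_023	lip_043	lip_001	lip_029	lip_078	pol_010	lip_070	lip_028	lip_116	lip_037
synthetic_pathway_11	synthetic set	pol_034	lip_113	pol_055	lip_086	lip_071	lip_110	lip_099	lip_051	lip_044	lip_049	lip_105	lip_060	pol_044	pol_068	lip_050	lip_135	lip_111	lip_020	lip_121	pol_012	pol_070	lip_053	pol_004	lip_100	lip_130	lip_048	lip_065	pol_069
synthetic_pathway_12	synthetic set	lip_124	lip_077	lip_098	pol_054	lip_019	lip_017
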