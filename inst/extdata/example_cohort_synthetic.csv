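athlete_id,sex,age_years,body_mass_kg,height_cm,ace_genotype,ppara_genotype,ckm_genotype,technique_min_wk,strength_min_wk,aerobic_min_wk
S001,F,28.1,50.4,172.3,ID,CG,AG,367.6,153.8,264.9
S002,F,20.6,70.6,171.8,ID,GG,AG,284,75.2,129.2
S003,F,30.6,58.8,161,DD,GG,AG,290,386.7,56.5
S004,F,16.8,58.1,176.9,ID,GG,AA,244.4,219.9,194.7
S005,F,27.2,64.7,168.6,II,GG,GG,216.6,161,82.7
S006,F,14.9,54.3,159.9,ID,CG,AA,411.6,257.4,115.1
S007,F,26.9,47.6,171.2,ID,GG,GG,426.2,56.4,100.6
S008,F,14,52.2,180.9,II,CG,AA,332.5,227.7,107.3
S009,F,25.8,85.9,175.1,ID,CG,GG,143.7,183.7,260.1
S010,F,23.2,78.4,186.2,DD,CG,AA,289.3,81.2,176.2
S011,F,27.9,68.1,165.1,ID,GG,AA,486.4,68.5,117.2
S012,F,14.2,91.2,159.2,ID,CG,AA,176.2,196.3,72.1
S013,M,30.7,98.1,161.9,ID,GG,AA,210.1,211.8,106
S014,M,35.2,57.8,183.5,ID,GG,AA,487.1,201,97.1
S015,M,27.6,92.9,153.8,ID,CG,AA,168.3,130.3,149.6
S016,M,21.5,46.2,184.2,ID,GG,AA,355.1,333.4,107.9
S017,M,28.5,74.3,182.4,ID,GG,AA,774.1,104.2,54.3
S018,M,25.4,71.1,183.5,DD,GG,AA,379.8,308.4,216.5
S019,M,17.5,79.7,176.9,II,GG,AG,197.1,43.3,312.9
S020,M,26.1,47,183.9,ID,CG,AG,52.7,322.9,205
S021,M,33,57.5,194.5,DD,CG,AA,481.6,17.2,175.7
S022,M,24.2,70.4,158.3,ID,GG,AA,305.3,137.9,130.9
S023,M,17.4,51.8,166.1,ID,GG,AG,300.8,71.4,11.1
S024,M,26.1,60.8,171.2,ID,CG,GG,354,314.5,81.3
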