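fine_region	macro_region
Precentral_R	frontal_R
Precentral_L	frontal_L
Frontal_Sup_R	frontal_R
Frontal_Sup_L	frontal_L
Frontal_Sup_Orb_R	frontal_R
Frontal_Sup_Orb_L	frontal_L
Frontal_Mid_R	frontal_R
Frontal_Mid_L	frontal_L
Frontal_Mid_Orb_R	frontal_R
Frontal_Mid_Orb_L	frontal_L
Frontal_Inf_Oper_R	frontal_R
Frontal_Inf_Oper_L	frontal_L
Frontal_Inf_Tri_R	frontal_R
Frontal_Inf_Tri_L	frontal_L
Frontal_Inf_Orb_R	frontal_R
Frontal_Inf_Orb_L	frontal_L
Rolandic_Oper_R	frontal_R
Rolandic_Oper_L	frontal_L
Supp_Motor_Area_R	frontal_R
Supp_Motor_Area_L	frontal_L
Olfactory_R	frontal_R
Olfactory_L	frontal_L
Frontal_Sup_Medial_R	frontal_R
Frontal_Sup_Medial_L	frontal_L
Frontal_Med_Orb_R	frontal_R
Frontal_Med_Orb_L	frontal_L
Rectus_R	frontal_R
Rectus_L	frontal_L
Paracentral_Lobule_R	frontal_R
Paracentral_Lobule_L	frontal_L
Cingulum_Ant_R	frontal_R
Cingulum_Ant_L	frontal_L
Cingulum_Mid_R	frontal_R
Cingulum_Mid_L	frontal_L
Hippocampus_R	temporomedial_R
Hippocampus_L	temporomedial_L
ParaHippocampal_R	temporomedial_R
ParaHippocampal_L	temporomedial_L
Amygdala_R	temporomedial_R
Amygdala_L	temporomedial_L
Fusiform_R	temporomedial_R
Fusiform_L	temporomedial_L
Insula_R	temporolateral_R
Insula_L	temporolateral_L
Heschl_R	temporolateral_R
Heschl_L	temporolateral_L
Temporal_Sup_R	temporolateral_R
Temporal_Sup_L	temporolateral_L
Temporal_Pole_Sup_R	temporolateral_R
Temporal_Pole_Sup_L	temporolateral_L
Temporal_Mid_R	temporolateral_R
Temporal_Mid_L	temporolateral_L
Temporal_Pole_Mid_R	temporolateral_R
Temporal_Pole_Mid_L	temporolateral_L
Temporal_Inf_R	temporolateral_R
Temporal_Inf_L	temporolateral_L
Postcentral_R	parietal_R
Postcentral_L	parietal_L
Parietal_Sup_R	parietal_R
Parietal_Sup_L	parietal_L
Parietal_Inf_R	parietal_R
Parietal_Inf_L	parietal_L
SupraMarginal_R	parietal_R
SupraMarginal_L	parietal_L
Angular_R	parietal_R
Angular_L	parietal_L
Precuneus_R	parietal_R
Precuneus_L	parietal_L
Cingulum_Post_R	parietal_R
Cingulum_Post_L	parietal_L
Calcarine_R	occipital_R
Calcarine_L	occipital_L
Cuneus_R	occipital_R
Cuneus_L	occipital_L
Lingual_R	occipital_R
Lingual_L	occipital_L
Occipital_Sup_R	occipital_R
Occipital_Sup_L	occipital_L
Occipital_Mid_R	occipital_R
Occipital_Mid_L	occipital_L
Occipital_Inf_R	occipital_R
Occipital_Inf_L	occipital_L
Thal_AV_R	thalamus_R
Thal_AV_L	thalamus_L
Thal_LP_R	thalamus_R
Thal_LP_L	thalamus_L
Thal_VA_R	thalamus_R
Thal_VA_L	thalamus_L
Thal_VL_R	thalamus_R
Thal_VL_L	thalamus_L
Thal_VPL_R	thalamus_R
Thal_VPL_L	thalamus_L
Thal_IL_R	thalamus_R
Thal_IL_L	thalamus_L
Thal_Re_R	thalamus_R
Thal_Re_L	thalamus_L
Thal_MDm_R	thalamus_R
Thal_MDm_L	thalamus_L
Thal_MDl_R	thalamus_R
Thal_MDl_L	thalamus_L
Thal_PuM_R	thalamus_R
Thal_PuM_L	thalamus_L
Thal_LGN_R	thalamus_R
Thal_LGN_L	thalamus_L
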