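name,kind,hemisphere
lh_bankssts_thickness,thickness,left
lh_caudalanteriorcingulate_thickness,thickness,left
lh_caudalmiddlefrontal_thickness,thickness,left
lh_cuneus_thickness,thickness,left
lh_entorhinal_thickness,thickness,left
lh_frontalpole_thickness,thickness,left
lh_fusiform_thickness,thickness,left
lh_inferiorparietal_thickness,thickness,left
lh_inferiortemporal_thickness,thickness,left
lh_insula_thickness,thickness,left
lh_isthmuscingulate_thickness,thickness,left
lh_lateraloccipital_thickness,thickness,left
lh_lateralorbitofrontal_thickness,thickness,left
lh_lingual_thickness,thickness,left
lh_medialorbitofrontal_thickness,thickness,left
lh_middletemporal_thickness,thickness,left
lh_paracentral_thickness,thickness,left
lh_parahippocampal_thickness,thickness,left
lh_parsopercularis_thickness,thickness,left
lh_parsorbitalis_thickness,thickness,left
lh_parstriangularis_thickness,thickness,left
lh_pericalcarine_thickness,thickness,left
lh_postcentral_thickness,thickness,left
lh_posteriorcingulate_thickness,thickness,left
lh_precentral_thickness,thickness,left
lh_precuneus_thickness,thickness,left
lh_rostralanteriorcingulate_thickness,thickness,left
lh_rostralmiddlefrontal_thickness,thickness,left
lh_superiorfrontal_thickness,thickness,left
lh_superiorparietal_thickness,thickness,left
lh_superiortemporal_thickness,thickness,left
lh_supramarginal_thickness,thickness,left
lh_temporalpole_thickness,thickness,left
lh_transversetemporal_thickness,thickness,left
rh_bankssts_thickness,thickness,right
rh_caudalanteriorcingulate_thickness,thickness,right
rh_caudalmiddlefrontal_thickness,thickness,right
rh_cuneus_thickness,thickness,right
rh_entorhinal_thickness,thickness,right
rh_frontalpole_thickness,thickness,right
rh_fusiform_thickness,thickness,right
rh_inferiorparietal_thickness,thickness,right
rh_inferiortemporal_thickness,thickness,right
rh_insula_thickness,thickness,right
rh_isthmuscingulate_thickness,thickness,right
rh_lateraloccipital_thickness,thickness,right
rh_lateralorbitofrontal_thickness,thickness,right
rh_lingual_thickness,thickness,right
rh_medialorbitofrontal_thickness,thickness,right
rh_middletemporal_thickness,thickness,right
rh_paracentral_thickness,thickness,right
rh_parahippocampal_thickness,thickness,right
rh_parsopercularis_thickness,thickness,right
rh_parsorbitalis_thickness,thickness,right
rh_parstriangularis_thickness,thickness,right
rh_pericalcarine_thickness,thickness,right
rh_postcentral_thickness,thickness,right
rh_posteriorcingulate_thickness,thickness,right
rh_precentral_thickness,thickness,right
rh_precuneus_thickness,thickness,right
rh_rostralanteriorcingulate_thickness,thickness,right
rh_rostralmiddlefrontal_thickness,thickness,right
rh_superiorfrontal_thickness,thickness,right
rh_superiorparietal_thickness,thickness,right
rh_superiortemporal_thickness,thickness,right
rh_supramarginal_thickness,thickness,right
rh_temporalpole_thickness,thickness,right
rh_transversetemporal_thickness,thickness,right
lh_bankssts_volume,volume,left
lh_caudalanteriorcingulate_volume,volume,left
lh_caudalmiddlefrontal_volume,volume,left
lh_cuneus_volume,volume,left
lh_entorhinal_volume,volume,left
lh_frontalpole_volume,volume,left
lh_fusiform_volume,volume,left
lh_inferiorparietal_volume,volume,left
lh_inferiortemporal_volume,volume,left
lh_insula_volume,volume,left
lh_isthmuscingulate_volume,volume,left
lh_lateraloccipital_volume,volume,left
lh_lateralorbitofrontal_volume,volume,left
lh_lingual_volume,volume,left
lh_medialorbitofrontal_volume,volume,left
lh_middletemporal_volume,volume,left
lh_paracentral_volume,volume,left
lh_parahippocampal_volume,volume,left
lh_parsopercularis_volume,volume,left
lh_parsorbitalis_volume,volume,left
lh_parstriangularis_volume,volume,left
lh_pericalcarine_volume,volume,left
lh_postcentral_volume,volume,left
lh_posteriorcingulate_volume,volume,left
lh_precentral_volume,volume,left
lh_precuneus_volume,volume,left
lh_rostralanteriorcingulate_volume,volume,left
lh_rostralmiddlefrontal_volume,volume,left
lh_superiorfrontal_volume,volume,left
lh_superiorparietal_volume,volume,left
lh_superiortemporal_volume,volume,left
lh_supramarginal_volume,volume,left
lh_temporalpole_volume,volume,left
lh_transversetemporal_volume,volume,left
rh_bankssts_volume,volume,right
rh_caudalanteriorcingulate_volume,volume,right
rh_caudalmiddlefrontal_volume,volume,right
rh_cuneus_volume,volume,right
rh_entorhinal_volume,volume,right
rh_frontalpole_volume,volume,right
rh_fusiform_volume,volume,right
rh_inferiorparietal_volume,volume,right
rh_inferiortemporal_volume,volume,right
rh_insula_volume,volume,right
rh_isthmuscingulate_volume,volume,right
rh_lateraloccipital_volume,volume,right
rh_lateralorbitofrontal_volume,volume,right
rh_lingual_volume,volume,right
rh_medialorbitofrontal_volume,volume,right
rh_middletemporal_volume,volume,right
rh_paracentral_volume,volume,right
rh_parahippocampal_volume,volume,right
rh_parsopercularis_volume,volume,right
rh_parsorbitalis_volume,volume,right
rh_parstriangularis_volume,volume,right
rh_pericalcarine_volume,volume,right
rh_postcentral_volume,volume,right
rh_posteriorcingulate_volume,volume,right
rh_precentral_volume,volume,right
rh_precuneus_volume,volume,right
rh_rostralanteriorcingulate_volume,volume,right
rh_rostralmiddlefrontal_volume,volume,right
rh_superiorfrontal_volume,volume,right
rh_superiorparietal_volume,volume,right
rh_superiortemporal_volume,volume,right
rh_supramarginal_volume,volume,right
rh_temporalpole_volume,volume,right
rh_transversetemporal_volume,volume,right
Left-Lateral-Ventricle,volume,left
Left-Inf-Lat-Vent,volume,left
Left-Cerebellum-White-Matter,volume,left
Left-Cerebellum-Cortex,volume,left
Left-Thalamus-Proper,volume,left
Left-Caudate,volume,left
Left-Putamen,volume,left
Left-Pallidum,volume,left
Left-Hippocampus,volume,left
Left-Amygdala,volume,left
Left-Accumbens-area,volume,left
Left-VentralDC,volume,left
Left-vessel,volume,left
Left-choroid-plexus,volume,left
Left-WM-hypointensities,volume,left
Left-non-WM-hypointensities,volume,left
Left-Cerebral-White-Matter,volume,left
Left-Cerebral-Cortex,volume,left
Left-Lesion,volume,left
Right-Lateral-Ventricle,volume,right
Right-Inf-Lat-Vent,volume,right
Right-Cerebellum-White-Matter,volume,right
Right-Cerebellum-Cortex,volume,right
Right-Thalamus-Proper,volume,right
Right-Caudate,volume,right
Right-Putamen,volume,right
Right-Pallidum,volume,right
Right-Hippocampus,volume,right
Right-Amygdala,volume,right
Right-Accumbens-area,volume,right
Right-VentralDC,volume,right
Right-vessel,volume,right
Right-choroid-plexus,volume,right
Right-WM-hypointensities,volume,right
Right-non-WM-hypointensities,volume,right
Right-Cerebral-White-Matter,volume,right
Right-Cerebral-Cortex,volume,right
Right-Lesion,volume,right
3rd-Ventricle,volume,bilateral
4th-Ventricle,volume,bilateral
5th-Ventricle,volume,bilateral
Brain-Stem,volume,bilateral
CSF,volume,bilateral
Optic-Chiasm,volume,bilateral
WM-hypointensities,volume,bilateral
non-WM-hypointensities,volume,bilateral
CC_Posterior,volume,bilateral
CC_Mid_Posterior,volume,bilateral
CC_Central,volume,bilateral
CC_Mid_Anterior,volume,bilateral
CC_Anterior,volume,bilateral
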