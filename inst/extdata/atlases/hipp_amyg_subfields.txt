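lh_Hippocampal_tail
lh_subiculum-body
lh_subiculum-head
lh_presubiculum-body
lh_presubiculum-head
lh_parasubiculum
lh_CA1-body
lh_CA1-head
lh_CA3-body
lh_CA3-head
lh_CA4-body
lh_CA4-head
lh_GC-ML-DG-body
lh_GC-ML-DG-head
lh_molecular_layer_HP-body
lh_molecular_layer_HP-head
lh_hippocampal-fissure
lh_fimbria
lh_HATA
lh_Lateral-nucleus
lh_Basal-nucleus
lh_Accessory-Basal-nucleus
lh_Anterior-amygdaloid-area-AAA
lh_Central-nucleus
lh_Medial-nucleus
lh_Cortical-nucleus
lh_Corticoamygdaloid-transitio
lh_Paralaminar-nucleus
rh_Hippocampal_tail
rh_subiculum-body
rh_subiculum-head
rh_presubiculum-body
rh_presubiculum-head
rh_parasubiculum
rh_CA1-body
rh_CA1-head
rh_CA3-body
rh_CA3-head
rh_CA4-body
rh_CA4-head
rh_GC-ML-DG-body
rh_GC-ML-DG-head
rh_molecular_layer_HP-body
rh_molecular_layer_HP-head
rh_hippocampal-fissure
rh_fimbria
rh_HATA
rh_Lateral-nucleus
rh_Basal-nucleus
rh_Accessory-Basal-nucleus
rh_Anterior-amygdaloid-area-AAA
rh_Central-nucleus
rh_Medial-nucleus
rh_Cortical-nucleus
rh_Corticoamygdaloid-transitio
rh_Paralaminar-nucleus
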