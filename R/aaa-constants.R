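# Canonical site order used throughout: 1 = L1-L4 spine, 2 = femoral neck,
# 3 = total hip.  Cohort tables carry the T-scores as t_l1l4, t_fneck,
# t_thip.
SITE_LABELS <- c("L1L4", "femoral_neck", "total_hip")
TSCORE_COLS <- c("t_l1l4", "t_fneck", "t_thip")
COHORT_REQUIRED <- c("patient_id", TSCORE_COLS)
DIAGNOSIS_LEVELS <- c("normal", "osteopenia", "osteoporosis")
RHO_GRID <- c(0, 0.2, 0.4, 0.6, 0.8)
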