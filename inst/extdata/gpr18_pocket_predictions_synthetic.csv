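model,residue
AF-DM,2.60
AF-DM,2.64
AF-DM,45.52
AF-DM,6.55
CF-DM,2.60
CF-DM,2.64
CF-DM,45.52
CF-DM,6.55
PF-DM,2.60
PF-DM,2.64
PF-DM,45.52
PF-DM,6.55
TR_1,2.60
TR_1,2.64
TR_1,45.52
TR_1,6.55
TTA_5,2.60
TTA_5,2.64
TTA_5,45.52
TTA_5,6.55
CIT_1,2.60
CIT_1,2.64
CIT_1,45.52
CIT_1,6.55
IT_1,2.60
IT_1,2.64
IT_1,45.52
IT_1,6.55
PY3_10,2.60
PY3_10,2.64
PY3_10,45.52
PY3_10,6.55
CF-DM,2.63
CF-DM,3.32
CF-DM,45.50
CF-DM,5.42
CF-DM,6.51
CF-DM,7.39
PF-DM,2.63
PF-DM,3.32
PF-DM,45.50
PF-DM,5.42
PF-DM,6.51
PF-DM,7.39
TR_1,2.63
TR_1,3.32
TR_1,45.50
TR_1,5.42
TR_1,6.51
TR_1,7.39
TTA_5,2.63
TTA_5,3.32
TTA_5,45.50
TTA_5,5.42
TTA_5,6.51
TTA_5,7.39
CIT_1,2.63
CIT_1,3.32
CIT_1,45.50
CIT_1,5.42
CIT_1,6.51
CIT_1,7.39
IT_1,2.63
IT_1,3.32
IT_1,45.50
IT_1,5.42
IT_1,6.51
IT_1,7.39
PY3_10,2.63
PY3_10,3.32
PY3_10,45.50
PY3_10,5.42
PY3_10,6.51
PY3_10,7.39
PF-DM,45.51
PF-DM,6.58
PF-DM,7.32
PF-DM,7.35
PF-DM,7.36
TR_1,45.51
TR_1,6.58
TR_1,7.32
TR_1,7.35
TR_1,7.36
TTA_5,45.51
TTA_5,6.58
TTA_5,7.32
TTA_5,7.35
TTA_5,7.36
CIT_1,45.51
CIT_1,6.58
CIT_1,7.32
CIT_1,7.35
CIT_1,7.36
IT_1,45.51
IT_1,6.58
IT_1,7.32
IT_1,7.35
IT_1,7.36
PY3_10,45.51
PY3_10,6.58
PY3_10,7.32
PY3_10,7.35
PY3_10,7.36
TR_1,A:175
TTA_5,A:175
PY3_10,A:175
TTA_5,A:176
IT_1,A:176
TTA_5,7.31
CIT_1,3.28
IT_1,3.28
PY3_10,3.28
TR_1,3.28
TTA_5,3.28
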