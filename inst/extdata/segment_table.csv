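"segment","proximal","distal","mass_fraction","com_position_fraction"
"head","neck","head_top",0.081,0.5
"upper_trunk","neck","spine",0.216,0.5
"lower_trunk","spine","sacrum",0.281,0.5
"upper_arm_left","shoulder_left","elbow_left",0.028,0.5
"upper_arm_right","shoulder_right","elbow_right",0.028,0.5
"forearm_left","elbow_left","wrist_left",0.016,0.5
"forearm_right","elbow_right","wrist_right",0.016,0.5
"thigh_left","hip_left","knee_left",0.1,0.5
"thigh_right","hip_right","knee_right",0.1,0.5
"shank_left","knee_left","ankle_left",0.0465,0.5
"shank_right","knee_right","ankle_right",0.0465,0.5
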