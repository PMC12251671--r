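name,fraction
ankle_height,0.039
calf,0.246
thigh,0.245
trunk,0.288
shoulder_to_crown,0.182
shoulder_to_nose,0.130
hip_width,0.120
shoulder_width,0.230
upper_arm,0.186
forearm,0.146
hand_length,0.108
foot_length,0.152
face_scale,0.040
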