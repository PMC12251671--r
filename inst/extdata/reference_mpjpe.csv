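table,method,metric,mpjpe_mm
benchmark,SimpleBaseline,whole_body,125.4
benchmark,SimpleBaseline,body,125.7
benchmark,SimpleBaseline,face,24.6
benchmark,SimpleBaseline,hands,42.5
benchmark,LargeSimpleBaseline,whole_body,112.3
benchmark,LargeSimpleBaseline,body,112.6
benchmark,LargeSimpleBaseline,face,14.6
benchmark,LargeSimpleBaseline,hands,31.7
benchmark,JointFormer,whole_body,88.3
benchmark,JointFormer,body,84.9
benchmark,JointFormer,face,17.8
benchmark,JointFormer,hands,43.7
benchmark,3D-LFM,whole_body,64.13
benchmark,3D-LFM,body,60.83
benchmark,3D-LFM,face,10.44
benchmark,3D-LFM,hands,28.22
benchmark,SemGAN,whole_body,47.87
benchmark,SemGAN,body,45.39
benchmark,SemGAN,face,15.95
benchmark,SemGAN,hands,27.77
benchmark,GravityConstrained,whole_body,44.49
benchmark,GravityConstrained,body,40.41
benchmark,GravityConstrained,face,6.09
benchmark,GravityConstrained,hands,22.07
constraint_ablation,mass_only,whole_body,67.50
constraint_ablation,mass_only,body,59.24
constraint_ablation,mass_only,face,10.10
constraint_ablation,mass_only,hands,29.41
constraint_ablation,cog_only,whole_body,58.34
constraint_ablation,cog_only,body,50.76
constraint_ablation,cog_only,face,8.32
constraint_ablation,cog_only,hands,25.73
constraint_ablation,mass_and_cog,whole_body,44.49
constraint_ablation,mass_and_cog,body,40.41
constraint_ablation,mass_and_cog,face,6.09
constraint_ablation,mass_and_cog,hands,22.07
loss_ablation,L,whole_body,59.71
loss_ablation,L,body,47.69
loss_ablation,L,face,15.35
loss_ablation,L,hands,31.93
loss_ablation,L_gd,whole_body,51.75
loss_ablation,L_gd,body,44.21
loss_ablation,L_gd,face,13.29
loss_ablation,L_gd,hands,25.61
loss_ablation,L_bone,whole_body,49.29
loss_ablation,L_bone,body,45.57
loss_ablation,L_bone,face,9.90
loss_ablation,L_bone,hands,26.61
loss_ablation,L_total,whole_body,44.49
loss_ablation,L_total,body,40.41
loss_ablation,L_total,face,6.09
loss_ablation,L_total,hands,22.07
per_action,JointFormer,walk,39.4
per_action,JointFormer,eat,46.6
per_action,GravityConstrained,walk,27.9
per_action,GravityConstrained,eat,33.6
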