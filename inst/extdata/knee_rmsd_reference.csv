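quantity,inter_session_rmsd,intra_session_rmsd
Rotation angle,3.12,1.99
Orientation of the rotation axis,6.35,3.01
Flexion-extension angle (Cardan),5.06,2.36
Projected attitude vector onto e1,5.05,2.34
Adduction-abduction angle (Cardan),2.21,0.59
Projected attitude vector onto e2,2.87,0.85
Internal-external rotation angle (Cardan),4.77,1.58
Projected attitude vector onto e3,4.58,1.50
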