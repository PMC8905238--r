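model,avg_p,avg_r,printed_f1
glcm_svm,22.05,48.11,30.24
color_svm,60.97,58.74,59.83
hog_svm,64.30,64.07,64.18
mc_svm,68.64,68.17,68.40
lbp_svm,74.28,73.73,74.00
cornseednet,95.63,95.29,95.46
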