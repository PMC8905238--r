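input,model,p_good,r_good,p_bad,r_bad,printed_avg_p,printed_avg_r,printed_f1,note
rgbnir,vgg16,90.91,96.55,95.19,92.86,93.05,94.71,93.87,
rgbnir,resnet50,94.00,97.24,95.37,91.96,94.69,94.60,94.64,
rgbnir,mobilenet,93.85,94.48,91.96,91.96,91.96,93.22,92.59,inconsistent_avg_p
rgbnir,densenet121,91.45,95.86,93.40,88.39,92.43,92.13,92.27,
rgbnir,xception,94.48,94.48,92.03,92.86,93.26,93.67,93.46,
rgbnir,cornseednet,94.08,98.62,97.17,91.96,95.63,95.29,95.46,
rgb,vgg16,90.13,94.48,93.20,85.71,91.67,90.10,90.87,
rgb,resnet50,95.56,95.86,93.52,90.18,94.54,93.02,93.77,
rgb,cornseednet,93.33,96.55,94.28,88.39,93.80,92.47,93.13,
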