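model,good_correct,bad_correct,total_per_class,printed_good_acc,printed_bad_acc,printed_avg_acc
vgg16,99,99,100,99,99,99.00
resnet50,100,98,100,100,98,99.00
mobilenet,97,99,100,97,99,98.00
densenet121,97,98,100,97,98,97.50
xception,98,97,100,98,97,97.50
cornseednet,100,100,100,100,100,100.00
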