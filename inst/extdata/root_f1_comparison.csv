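model,root_f1
improved_unet,58.71
pspnet,25.28
segnet,23.94
deeplabv3plus,25.91
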