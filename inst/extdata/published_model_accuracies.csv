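pair,neuropsychological,mri,combined
CN versus AD,0.922,0.842,0.939
CN versus EMCI,0.846,0.616,0.856
CN versus LMCI,0.885,0.714,0.908
EMCI versus LMCI,0.634,0.688,0.706
EMCI versus AD,0.932,0.814,0.945
LMCI versus AD,0.898,0.596,0.901
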