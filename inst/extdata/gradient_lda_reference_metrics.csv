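metric,class,value
specificity,fat,0.69
specificity,skin,0.94
specificity,nerve,0.94
specificity,bone,0.77
specificity,muscle,0.85
sensitivity,fat,0.89
sensitivity,skin,0.84
sensitivity,nerve,0.88
sensitivity,bone,0.74
sensitivity,muscle,0.75
specificity,average,0.83
sensitivity,average,0.82
accuracy,all,0.818
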