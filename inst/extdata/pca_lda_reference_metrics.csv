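metric,class,value
specificity,fat,0.98
specificity,skin,1.00
specificity,nerve,1.00
specificity,bone,0.99
specificity,muscle,1.00
sensitivity,fat,1.00
sensitivity,skin,1.00
sensitivity,nerve,1.00
sensitivity,bone,0.99
sensitivity,muscle,0.99
specificity,average,0.99
sensitivity,average,0.99
accuracy,all,0.993
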