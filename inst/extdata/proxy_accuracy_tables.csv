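measure,tn,fp,fn,tp,sens_pct,spec_pct
current,3012,72,199,71,26.3,97.7
future,2500,640,126,156,55.3,79.6
historical,3233,127,217,64,22.8,96.2
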