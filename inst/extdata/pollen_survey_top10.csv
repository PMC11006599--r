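compound_id,conc_mean,conc_median,conc_p90,n_detect,n_sites
indoxacarb,1310,57,3380,17,106
spinosad,658,658,1170,2,106
chlorpyrifos-ethyl,282,13.9,561,9,106
deltamethrin,68.8,68.8,117,2,106
dimethoate,31,15.4,77.3,11,106
imidacloprid,9.49,8.1,17.5,9,106
cyfluthrin,41.5,41.5,41.5,1,106
dithianon,3300,244,12900,25,106
etofenprox,61.9,47.5,91.9,3,106
chlorpyrifos-methyl,36.9,16.6,80.9,4,106
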