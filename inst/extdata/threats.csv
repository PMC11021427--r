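threat,max_dist_km,weight,decay
agriculture,8,0.82,linear
livestock_grazing,6,0.72,linear
urban,8,0.31,exponential
rural,8,0.51,exponential
mining,10,0.69,exponential
main_roads,7,0.50,linear
minor_roads,5,0.50,linear
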