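sex,cell_type,mean_count,cv_percent,n_animals
female,neuron,10312,5.03,16
male,neuron,9396,5.59,15
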