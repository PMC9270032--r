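line,sex,cell_type,mean_count,cv_percent,n_animals
brp,female,neuron,10776,2.65,6
Syt1,female,neuron,10097,5.96,5
nSyb,female,neuron,9971,1.35,5
brp,male,neuron,9888,3.15,5
Syt1,male,neuron,9012,3.8,5
nSyb,male,neuron,9286,5.38,5
repo,female,glia,3860,3.37,7
repo,male,glia,4015,1.98,6
Sh,male,channel,8204,5.67,10
Shal,male,channel,8261,3.1,5
Shab,male,channel,3057,8.21,10
Shaw,male,channel,1737,4.3,11
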