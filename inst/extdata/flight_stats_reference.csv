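flight,model,t_min,t_max,t_mean,t_sd,t_wet,t_dry,n,spacing_cm
nadir,ortho,31.9,54.4,37.9,3.42,32.5,50.7,66945,1.57
nadir,cloud,31.7,56.2,38.9,3.69,33.5,51.5,215199,5.58
oblique,ortho,31.4,44.8,34.9,1.86,31.8,41.9,47717,1.91
oblique,cloud,31.0,43.2,35.2,1.64,31.9,41.3,181372,6.64
combined,ortho,31.8,55.5,38.3,3.83,32.5,51.8,53315,1.79
combined,cloud,31.1,55.0,36.4,2.72,32.2,50.1,208687,6.04
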