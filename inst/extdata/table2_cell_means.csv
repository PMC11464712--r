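roi,reader,session,mean_pa_deg
anterior,1,1,14.3
anterior,1,2,15.1
anterior,1,3,15.3
anterior,2,1,15.6
anterior,2,2,16.0
anterior,2,3,16.6
anterior,3,1,15.4
anterior,3,2,15.8
anterior,3,3,16.5
posterior,1,1,10.4
posterior,1,2,10.6
posterior,1,3,10.8
posterior,2,1,11.2
posterior,2,2,10.8
posterior,2,3,11.0
posterior,3,1,10.2
posterior,3,2,10.3
posterior,3,3,10.6
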