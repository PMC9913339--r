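chi_max,alpha_d,T,tau,omega0,chi0,s_chi
1.0,10.0,1.0,0.08,1.0,0.2,0.05
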