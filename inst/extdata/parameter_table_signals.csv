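row,alpha_a,alpha_m,beta,gamma
fig1a,0.5,1.0,2.0,1.0
fig1b,1.0,1.0,2.0,1.0
fig2a,0.5,1.0,2.0,1.0
fig2b,1.0,1.0,2.0,1.0
fig2c,0.4,0.4,2.0,1.0
fig2d,1.0,1.0,2.0,1.0
fig3a,1.0,1.0,2.0,1.0
fig5ac,1.0,1.0,2.0,4.0
fig5d,1.0,1.0,2.0,1.0
fig6a,0.7,1.0,4.0,1.0
fig6b,1.0,1.0,3.0,1.0
fig7a,1.0,0.5,2.0,3.0
fig7b,1.0,1.0,2.0,1.0
fig8a,1.0,0.5,2.0,3.0
fig8b,0.7,1.0,4.0,1.0
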