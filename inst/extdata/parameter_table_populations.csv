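row,eta,psi,d,q0
fig1a,5.0,1.0,1.2,0.5
fig1b,5.0,1.0,0.2,1.0
fig2a,5.0,1.0,1.2,0.5
fig2b,5.0,1.0,0.2,1.0
fig2c,2.0,1.0,0.4,1.0
fig2d,5.0,1.0,0.2,1.0
fig3a,5.0,1.0,0.2,1.0
fig5ac,2.0,1.0,0.95,1.0
fig5d,1.75,1.0,0.8,1.0
fig6a,4.0,1.0,1.2,1.0
fig6b,1.0,1.0,0.8,1.0
fig7a,5.0,1.0,0.9,1.0
fig7b,5.0,1.0,0.2,1.0
fig8a,5.0,1.0,0.9,1.0
fig8b,4.0,1.0,1.2,1.0
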