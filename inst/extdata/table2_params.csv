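# best-fit buildup-tail parameters per photon energy
energy,n,mu
4MV,0.17,0.0605
6MV,0.208,0.0515
10MV,0.495,0.0458
18MV,1.2,0.0422
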