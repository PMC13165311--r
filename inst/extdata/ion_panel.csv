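canonical_id,hsab_class,e0_volts,couple,paramagnetic,heavy_atom,source_note
Fe(III),hard,0.771,Fe3+/Fe2+,TRUE,FALSE,E0 to the stable aqueous Fe(II) state; d5 high-spin aqua ion
Cr(VI),hard,1.33,Cr2O7(2-)/Cr3+,FALSE,FALSE,E0 of dichromate to Cr(III) in acid; d0
Cu(II),borderline,0.342,Cu2+/Cu,TRUE,FALSE,reduction to metal; d9
Hg(II),soft,0.851,Hg2+/Hg,FALSE,TRUE,reduction to metal; d10; period 6
Ag(I),soft,0.800,Ag+/Ag,FALSE,TRUE,reduction to metal; d10; period 5
Pb(II),borderline,-0.126,Pb2+/Pb,FALSE,TRUE,reduction to metal; 6s2 closed shell; period 6
Cd(II),soft,-0.403,Cd2+/Cd,FALSE,TRUE,reduction to metal; d10; period 5
Zn(II),borderline,-0.762,Zn2+/Zn,FALSE,FALSE,reduction to metal; d10
Ni(II),borderline,-0.257,Ni2+/Ni,TRUE,FALSE,reduction to metal; d8
Co(II),borderline,-0.280,Co2+/Co,TRUE,FALSE,reduction to metal; d7
Mn(II),hard,-1.185,Mn2+/Mn,TRUE,FALSE,reduction to metal; d5 high-spin
Fe(II),borderline,-0.447,Fe2+/Fe,TRUE,FALSE,reduction to metal; d6 high-spin
Al(III),hard,-1.662,Al3+/Al,FALSE,FALSE,reduction to metal; closed shell
Mg(II),hard,-2.372,Mg2+/Mg,FALSE,FALSE,reduction to metal; closed shell
Ca(II),hard,-2.868,Ca2+/Ca,FALSE,FALSE,reduction to metal; closed shell
Na(I),hard,-2.710,Na+/Na,FALSE,FALSE,reduction to metal; closed shell
K(I),hard,-2.931,K+/K,FALSE,FALSE,reduction to metal; closed shell
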