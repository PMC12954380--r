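name,Em_mV,source
MK-7,-70,membrane menaquinone-7 pool of K. stuttgartiensis
NAD(P),-320,"NAD(P)+/NAD(P)H couple, standard conditions pH 7"
nitrite/NO,380,nitrite reduction to nitric oxide
Kuste4569,303,"OTTLE spectropotentiometry, soluble Rieske domain"
Kustd1480,335,"OTTLE spectropotentiometry, soluble Rieske domain"
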