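label,structure,E_elst,E_exch,E_ind,E_disp,E_total
D1,experimental,-15.730,13.619,-4.656,-5.380,-12.146
E1,experimental,-27.448,33.520,-12.021,-8.788,-14.736
D2,optimized,-24.472,27.813,-10.886,-8.037,-15.582
E2,optimized,-35.921,46.756,-21.032,-10.774,-20.970
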