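(g02:0.03875668343,(g04:0.04109915628,(g06:0.01607752381,(g05:0.02457305034,(g01:0.02614001541,g03:0.03687887225):0.03880379614):0.02799615836):0.03993362487):0.01763086495);
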