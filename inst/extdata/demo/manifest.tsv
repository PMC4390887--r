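g02	g02.faa
g04	g04.faa
g06	g06.faa
g05	g05.faa
g01	g01.faa
g03	g03.faa
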