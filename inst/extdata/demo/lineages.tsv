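g02	<D>tax_g02<P>tax_g02<C>tax_g02<O>tax_g02<F>tax_g02<G>Unclassified<S>Unclassified
g04	<D>tax_n8<P>tax_g04<C>tax_g04<O>tax_g04<F>tax_g04<G>tax_g04<S>tax_g04
g06	<D>tax_n8<P>tax_n9<C>tax_g06<O>tax_g06<F>tax_g06<G>tax_g06<S>tax_g06
g05	<D>tax_n8<P>tax_n9<C>tax_n10<O>tax_g05<F>tax_g05<G>tax_g05<S>tax_g05
g01	<D>tax_n8<P>tax_n9<C>tax_n10<O>tax_n11<F>tax_g01<G>tax_g01<S>tax_g01
g03	<D>tax_n8<P>tax_n9<C>tax_n10<O>tax_n11<F>tax_g03<G>tax_g03<S>tax_g03
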