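# Two example genomes in the UniMoG dialect.
# A: resolved homology if markers 1/3 and 2/4 are declared homologous
#    (one circular chromosome; "|" would end a linear one).
# B: a natural genome -- family 1 has three copies.
>A
1 2 4 3 )
>B
1 2 1 1 3 )
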