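>zma-miR528a-5p
TGGAAGGGGCATGCAGAGGAG
>zma-miR528b-5p
TGGAAGGGGCATGCAGAGGAG
>cca-miR390
AAGCTCAGGAGGGATAGCG
>lus-miR390a
AAGCTCAGGAGGGATAGCGCC
>lus-miR390b
AAGCTCAGGAGGGATAGCGCC
>csi-miR390b-5p
AGCTCAGGAGGGATAGCGCC
>lus-miR390c
AAGCTCAGGAGGGATAGCGCC
>ppt-miR390c-5p
AGCTCAGGAGGGATAGCGCC
>lus-miR390d
AAGCTCAGGAGGGATAGCGCC
>gma-miR390e
AGCTCAGGAGGGATAGCGCC
>gma-miR390f
AAGCTCAGGAGGGATAGCGCC
>gma-miR390g
AAGCTCAGGAGGGATAGCGCC
>atr-miR390.1
TAAAGCTCAGGAGGGATAGCG
>ath-miR414
GACGATGATGATGAAGATGA
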