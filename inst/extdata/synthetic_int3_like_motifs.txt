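# synthetic ESE-like hexamer set (84 motifs)
# purine/adenine-rich stand-in generated for testing; not an experimentally derived set
AAACAG
CGGGTA
ACGACA
TTCGGT
GACAGA
AGCACG
GAAAAC
GAACTG
TAAGTC
TATAAA
GGAAAT
ATGCAG
GACGGC
AAGGGT
ATGACC
TTCCAT
CCGGAA
TCTATT
AGGGAA
ATTGCC
TACCTC
TGAAGG
ATAAAA
TGGAAG
AACAGT
AAAGAT
AACTTA
TACATG
GAGAAT
GCAGCA
GAGATG
GCACGC
CATTGA
GAAACT
ACAATA
GCCATG
GAGGCA
ACCTGC
GTACAT
AACAAT
TAACTA
TGATAG
GAGGAA
CGTTCA
CCGCGA
ATCATA
GCCGAC
GGAGCC
TCAAAA
TGACTA
CTAATA
ACTTCG
GAAAGG
GAAGGT
ATGTCC
TTCAAC
GGCAGA
AAGAAT
GAACGT
TATGAA
AGAACT
ACACTA
AGATAG
AGTCAA
GCAAAA
AATAGC
AAAGAC
CAATAC
CCAAAT
GAGGTT
CCGAGA
CCCGAA
GAACAT
AACGGT
CAGGGT
CACGCA
AGGGGA
AGCTCG
TTAAGA
CAAAGG
AGAACA
GACTGA
TAAAGA
GAAATC
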