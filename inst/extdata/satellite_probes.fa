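>red_deer_satellite_I_probe Southern blot probe, satellite I consensus, 725 nt
CAAGACGAAAGGATGTCTGAATCCCCTGTGGAGACCACAGAGAAAGACCTAGTTCCCCACCTCATCGCGA
CCGGAGGCCTCACATCCTTTGAAAACTCCAGAGGTACGCGGAGATCAGTGCCTCCAAAGGAGACGATGCC
TGACTCCTCGTGAAACTTGATAGGAGTCCCAGGATTCCTGTGGCACGTGGAAAGGGACCCTTGGTCTCCC
GCCTCAGCTGGAGAGGCGTCCCAATTGCCCTGCCAAGCCTCGAGGAGAATCCCGAGTTGTCCCTCGCAAC
TAGGCAGGAGTCCTGACGTCGCTGAAGAAACACGTGTGTGGAAGGGCCATCCCCGTCGTAACTCGAGAAT
ATACCCCAGGTTCCCGCCGCAACTCGAGAAAAACCATGAGACTTCCCCCTCGCCGCGAGATGAGGCCCGA
TTCCCCTGCACTGCGTGCAGAGCAATTCCGTGTTGCACATCACACATGAAAGGAGCCTTGATTTCCTTGA
TGGCACTCCAGAGAAACCCCAAGAACACTGTTTCAAGGCTAGAGGGATCCTGAGGTCACTGTAGCAACAC
GAAAGAGCTCCGTGGACCAAAAATCAACTCGAGATGAGAGGTTAGTCCCTGGCTTCGACTCCAGAGGAAT
ACCACCTTACCACAAGCACCTCAAGAGGAGGCTTCTCTCAGCTCTAGGTATGTGAGAGGGACCCTGAGTT
TGCGGCCTCAAGTGGAATGGACACC
>mouse_major_satellite_probe Southern blot probe, cloned amplicon with vector flanks, 804 nt
CAGTGAGCGCGCGTAATACGACTCACTATAGGGCGAATTGGAGCTCCCGCGGTGCGGCCGCTCTAGAACT
AGTGGATCCCCCGGGCTGCAGCCCAATGTGGAATTCGCCCTTGGCGAGGAAAACTGAAAAAGGTGGAAAA
TTTAGAAATGTCCACTGTAGGACGTGGAATATGGCAAGAAAACTGAAAATCATGGAAAATGAGAAATATC
CACTTGACGACTTGAAAAATGACAAAATCCCTGAAAAACGTGAAAAATGAGAAATGCACACTGTAGGACC
TGGAATATGGCGAGAAAACTGAAAATCACGGAAAATGAGAAATACACACTTTAGGATGTGAAATATGGCG
AGGAAAACTGAAAAAGGTGGGAAATTTAGAAACGTCCACTGTAGGACGTGGAATATGGCAAGAGAACTGA
AAATCATGGAAAATGAGAAACATCCACTTGACGACTTGAAAAATGACGAAATCACTAAAAAACGTGAAAA
ATGAGAAATGCACACTGAAGGACCTGGAATATGGCGAGAAAACTGAAAATCACGGAAAATGAGAGATACA
CACTTTAGGACGTGAAATATGGCGAGGAAAACTGAAAAAGGTGGAAAATTTAGAAATGTCCTGTGTAGGA
CGTGGAATATGGCAAGAAAACTGAAAATCATGGAAAATGAGAAACATCCACTTGACGACTAAGGGCGAAT
TCCACAGTGGATATCAAGCTTATCGATACCGTCGACCTCGAGGGGGGGCCCGGTACCCAGCTTTTGTTCC
CTTTAGTGAGGGTTAATTGCGCGCTTGGCGTAAT
>mouse_major_satellite_fish_probe FISH oligo, 23 nt
GGAAAATTTAGAAATGTCCACTG
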