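>SYNTH_VGSC_reference_TTA synthetic Vgsc cDNA template, reference variant, 1014 codon TTA
CTAGCCTCGCAGGTGGCTACGGGTTCCCTTCGTCCCAACAATCTGACGTTTGTGCTCTGCGATTATCAGG
TATCACTGTACTAAGCGAGACGAACATCTCGGAGTATGTAAGGTAGGGGCTTGAATGCAGTGACCGTTAT
TTCAGCTACCAGGGCATAAAACGGCGTGCATCCAAGCGTTGGCCCCATTAGTACCGTATGAAAGTTTCCT
TTGCGACGCCGATGTCGACCATAAGCGTCGCGGTGATATGTTTTTAAAAAACTAAAGCCCTGACTTGTTT
CCTGCATTCCGTTCTTCTTGAGGGGATACAGGGACCGAGGAAGTAAGAAGGTAGTGATAGGAAACTTAGT
CGTACTTAACCGATGTATTAGTTCCAGACATTCTGCGAAGTCCAACGAAACGAACAAGATCGCCGGGAGA
CACTTGATAGGCAACCTTCTGAATATGCGTAGC
>SYNTH_VGSC_reference_TTT synthetic Vgsc cDNA template, reference variant, 1014 codon TTT
CTAGCCTCGCAGGTGGCTACGGGTTCCCTTCGTCCCAACAATCTGACGTTTGTGCTCTGCGATTATCAGG
TATCACTGTACTAAGCGAGACGAACATCTCGGAGTATGTAAGGTAGGGGCTTGAATGCAGTGACCGTTAT
TTCAGCTACCAGGGCATAAAACGGCGTGCATCCAAGCGTTGGCCCCATTAGTACCGTATGAAAGTTTCCT
TTGCGACGCCGATGTCGACCATAAGCGTCGCGGTGATATGTTTTTAAAAAACTAAAGCCCTGACTTGTTT
CCTGCATTCCGTTCTTCTTGAGGGGATACAGGGACCGAGGAAGTAAGAAGGTAGTGATAGGAAACTTTGT
CGTACTTAACCGATGTATTAGTTCCAGACATTCTGCGAAGTCCAACGAAACGAACAAGATCGCCGGGAGA
CACTTGATAGGCAACCTTCTGAATATGCGTAGC
>SYNTH_VGSC_conserved_flanks_TTA synthetic Vgsc cDNA template, conserved_flanks variant, 1014 codon TTA
GATCGGAGCGTCCACCGATGCCCAAGGGAAGCAGGGTTGTATCTGACGTTTGTGCTCTGCGATTATCAGG
TATCACTGTACTAAGCGAGACGAACATCTCGGAGTATGTAAGGTAGGGGCTTGAATGCAGTGACCGTTAT
TTCAGCTACCAGGGCATAAAACGGCGTGCATCCAAGCGTTGGCCCCATTAGTACCGTATGAAAGTTTCCT
TTGCGACGCCGATGTCGACCATAAGCGTCGCGGTGATATGTTTTTAAAAAACTAAAGCCCTGACTTGTTT
CCTGCATTCCGTTCTTCTTGAGGGGATACAGGGACCGAGGAAGTAAGAAGGTAGTGATAGGAAACTTAGT
CGTACTTAACCGATGTATTAGTTCCAGACATTCTGCGAAGTCCAACGAAACGAACAAGATCGCGCCCTCT
GTGAACTATCCGTTGGAAGACTTATACGCATCG
>SYNTH_VGSC_divergent_TTA synthetic Vgsc cDNA template, divergent variant, 1014 codon TTA
CTAGCCTCGCAGGTGGCTACGGGTTCCCTTCGTCCCAACAATCTGACGTTTGTGCTCTGCGATTATCAGG
TATCGCTGTACTAAGCGAGACGAACATCTTGGAGTATGTAAGGTAGGGGCTTGAGTGCAGTGACCGTTAT
TTCAGCTACTAGGGCATAAAACGGCGTGCATCCAGGCGTTGGCCCCATTAGTACCGTATAAAAGTTTCCT
TTGCGACGCCGATGCCGACCATAAGCGTCGCGGTGATATATTTTTAAAAAACTAAAGCCCTGACTTGTTT
CCTGCATTCCGTTCTTCTTGAGGGAATACAGGGACCGAGAAAGTAAGAAGGTAGTGATAGGAAACTTAGC
CGTACTCAACCGATATATTAGTTCTAGACATTCTACGAAGTCCAACGAAACGAACAAGATCGCCGGGAGA
CACTTGATAGGCAACCTTCTGAATATGCGTAGC
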