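name,role,sequence,reporter
RTSeq_Fwd,forward,ATCTGACGTTTGTGCTCTGC,
RTkdr_Fwd,forward,CCTGCATTCCGTTCTTCTTG,
RTkdr_Rev,reverse,GCGATCTTGTTCGTTTCGTT,
RTkdr_TTA,probe,FAM-GGTTAAGTA/ZEN/CGACTAAGTTTCCTATCACTAC-3IABkFQ,FAM
RTkdr_TTT,probe,HEX-GGTTAAGTA/ZEN/CGACAAAGTTTCCTATCACTAC-3IABkFQ,HEX
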