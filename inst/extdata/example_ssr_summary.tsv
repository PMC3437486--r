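label	value
Total number of TUSs examined	103215
Total size of examined sequences (bp)	34718996
Total number of identified SSRs	26252
Number of SSR containing sequences	23330
Number of sequences containing >1 SSR	2480
Number of SSRs present in compound formation	2012
Mono-nucleotide repeats	24428
Di-nucleotide repeats	743
Tri-nucleotide repeats	893
Tetra-nucleotide repeats	91
Penta-nucleotide repeats	51
Hexa-nucleotide repeats	46
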