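>region1|Col
CATCAACTACTTCATCAACTACTTCGTCATCAACTACTTACTGCAGCTGCATCAACTACTTCATCAAACG
TCTACTTCATACAGCTGCAACTAAATATATATATATATATATATATATATATATATATATATA
>region1|Ler
CATCAACTACTTCATCAACTACTTCGTCATCAACTACTTGCTGCAGCTGCATCAACTACTTCATCAAGCG
TCTACTTCATGCAGCTGCAACTAGATATATATATATATATATATATATATATATATATATATA
>region2|Col
CGTCGTCGTCGTCTGCAGCATCAACTACTTCATCAACTACTTCATCAACTACTTCATACGTCGTCGTCTG
CAGCAACTACTTCATCAACTACTTCATCAACTAACGTCGTCGTCTGCAGCTTCATCAACTACTTCATCAA
CTACTTCATATATATATATATATATATATATATATATATATATATATATATATATATATAT
>region2|Ler
CGTCGTCGTCGTCTGCAGCATCAACTACTTCATCAACTACTTCATCAACTACTTCATGCGTCGTCGTCTG
CAGCAACTACTTCATCAACTACTTCATCAACTAGCGTCGTCGTCTGCAGCTTCATCAACTACTTCATCAA
CTACTTCATATATATATATATATATATATATATATATATATATATATATATATATATATAT
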