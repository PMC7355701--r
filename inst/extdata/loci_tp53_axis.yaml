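- locus_id: TP53_rs1042522
  gene: TP53
  allele_wt: Arg
  allele_var: Pro
  genotype_labels:
  - Arg/Arg
  - Arg/Pro
  - Pro/Pro
- locus_id: MDM2_rs2279744
  gene: MDM2
  allele_wt: T
  allele_var: G
  genotype_labels:
  - TT
  - TG
  - GG
- locus_id: MDM2_rs3730485
  gene: MDM2
  allele_wt: I
  allele_var: D
  genotype_labels:
  - II
  - ID
  - DD
- locus_id: MDM4_rs4245739
  gene: MDM4
  allele_wt: C
  allele_var: A
  genotype_labels:
  - CC
  - AC
  - AA
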