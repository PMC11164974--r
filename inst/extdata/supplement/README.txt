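Drop-in location for the published supplementary matrices used by the
headline checks in tests/testthat/test-acceptance.R. These tables are not
redistributed with the package. Expected files, all TSV with a header row
and sample ids in the first column:

  tableS5_y_genotypes.tsv      samples x Y-SNP haploid calls (0/1, NA for
                               missing); includes the moose outgroup row
                               named "moose"
  tableS6_mtdna_genotypes.tsv  samples x mtDNA SNP calls, same coding
  tableS2_sample_groups.tsv    columns: sample, group (Table 1 group labels,
                               e.g. "Eurasia domesticated")
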