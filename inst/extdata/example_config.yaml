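# Example pipeline configuration.  Paths are relative to this file;
# point them at a study written by write_study().
genotypes: genotypes.tsv
expression:
  glucose: expression_glucose.tsv
  ethanol: expression_ethanol.tsv
threshold: 1.0e-5        # fixed genome-wide p-value threshold
target_fdr: 0.05         # used instead when threshold is omitted
perm_P_s: 200            # phenotypes sampled for the permutation null
perm_R: 100              # permutations per sampled phenotype
peak_window_bp: 25000
cis_bp: 150000
candidate_window_bp: 10000
min_class: 2
seed: 1
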