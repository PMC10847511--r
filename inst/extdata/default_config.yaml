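# Default analysis constants.
# hr_gene_panel: the 29 homologous-recombination-related genes whose
#   deleterious mutations define HR-pathway alteration.
# predictors: the 10 functional-impact prediction methods that must all
#   call a missense variant deleterious/damaging for it to be retained.
# drug_categories: the 24 drug classes used to group assays.
hr_gene_panel:
  - ATM
  - ATR
  - BARD1
  - BLM
  - BRCA1
  - BRCA2
  - BRIP1
  - CDK12
  - CHEK1
  - CHEK2
  - FANCA
  - FANCC
  - FANCD2
  - FANCE
  - FANCF
  - FANCI
  - FANCL
  - FANCM
  - MRE11
  - NBN
  - PALB2
  - RAD50
  - RAD51
  - RAD51B
  - RAD51C
  - RAD51D
  - RAD52
  - RAD54L
  - RPA1
predictors:
  - SIFT
  - Polyphen2
  - LRT
  - MutationTaster
  - MutationAssessor
  - FATHMM
  - PROVEAN
  - MetaSVM
  - MetaLR
  - M-CAP
drug_categories:
  - Platinum
  - PARP inhibitor
  - Topoisomerase inhibitor
  - DNA alkylator
  - DNA inhibitor
  - Antimetabolite
  - PI3K/MTOR signaling
  - RTK signaling
  - Chromatin-related
  - ERK MAPK signaling
  - Cell cycle-related
  - Anti-microtubular
  - Protein stability and degradation
  - Apoptosis regulation
  - EGFR signaling
  - WNT signaling
  - Genome integrity
  - Metabolism
  - Hormone-related
  - IGF1R signaling
  - p53 pathway
  - Cytoskeleton
  - JNK and p38 signaling
  - Others
damaging_label: damaging
methylation_ccle:
  beta_threshold: 0.3
  expr_percentile: 10
  n_regions: 2
methylation_clp:
  beta_threshold: 0.2
  expr_percentile: 30
  min_probes: 15
  n_probes: 17
association:
  min_altered: 10
  alpha: 0.05
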