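# Column-name maps from canonical fields to file columns, one map per dialect.
# A null entry means the dialect does not carry that field.
canonical:
  snp: snp
  chr: chr
  pos: pos
  ea: ea
  oa: oa
  eaf: eaf
  beta: beta
  se: se
  pval: pval
  "n": "n"
# Layout of MiBioGen-style per-taxon mbQTL association files.
mibiogen-like:
  snp: rsID
  chr: chr
  pos: bp
  ea: eff.allele
  oa: ref.allele
  eaf: EAF
  beta: beta
  se: SE
  pval: P.weightedSumZ
  "n": "N"
# Layout of FinnGen-style release files; these carry no per-SNP sample size,
# so `n` is filled from trait metadata at read time.
finngen-like:
  snp: rsids
  chr: "#chrom"
  pos: pos
  ea: alt
  oa: ref
  eaf: af_alt
  beta: beta
  se: sebeta
  pval: pval
  "n": ~
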