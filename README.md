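# scfvlib

Design and quality control of semisynthetic scFv phage-display antibody
libraries built by oligonucleotide-directed (Kunkel) mutagenesis of the
heavy- and light-chain CDR3 loops.

## Who this is for

Groups building synthetic or semisynthetic antibody libraries face the same
chain of desk work around the bench protocol: choose degenerate codons for
each CDR3 position, account for the theoretical diversity the design can
reach, QC the mutagenesis oligos, verify that the parental template can be
depleted by restriction digestion, check the sequenced repertoire against
the design, and triage panning/ELISA screening output. `scfvlib` covers
that chain end to end, plus a seeded synthetic-data generator with ground
truth so every step can be exercised offline.

## The model at the core

A CDR3 cassette is an ordered run of degenerate codons, each written in
IUPAC ambiguity letters (N = A/C/G/T, K = G/T, D = A/G/T, R = A/G,
Y = C/T) and realized by drawing one base uniformly and independently per
position. For a cassette with codons \(c_1 \dots c_k\):

- DNA diversity is the exact product of expansion counts
  \(\prod_i |c_i|\) (computed in arbitrary-precision integers: a 28-codon
  NNK run has \(32^{28} \approx 1.4\times10^{42}\) variants);
- each codon induces an amino-acid distribution by translating its
  expansion under the standard genetic code (an amber-suppressed mode
  translates TAG as Gln for supE display hosts); NNK reaches all 20
  residues with a single stop (TAG) at mass 1/32;
- the stop-free protein diversity is the product of per-position distinct
  non-stop residue counts, and the stop-free fraction of a k-NNK cassette
  is \((31/32)^k\).

The shipped design mirrors a VH3–Vκ1 scFv scaffold: a VL CDR3 spanning
Kabat 91–96 in two variants (Tyr91 fixed vs NNK, then DRC–RRY–NNK, fixed
Pro95, NNK), and VH CDR3 cassettes placing k NNK codons between the
conserved Arg94/Asp101 salt-bridge anchors — a short sublibrary (S,
k = 5–22) and a long one (L, k = 9–28), Kabat insertion letters
95…100a…100z. The parental template carries unique SacI (VL CDR3) and
NheI (VH CDR3) sites so unmutated plasmid can be excised; site checks,
regeneration-risk estimates, residual-template detection, per-position
entropy/logo matrices, Jensen–Shannon comparison to a natural-repertoire
reference, colony-count library sizing, panning enrichment ratios and the
≥4-fold ELISA hit rule are all implemented as small composable functions.

## Worked example

```r
library(scfvlib)

design <- library_design()
theoretical_library_stats(design)
#> <theoretical library diversity, standard code>
#>   VL: 2 cassettes, DNA 1.622e+06, stop-free protein 2.016e+05
#>   S: 18 cassettes, DNA 1.339e+33, stop-free protein 4.415e+28
#>   L: 20 cassettes, DNA 1.438e+42, stop-free protein 2.825e+36
#>   combined (VL x VH): DNA 2.333e+48, protein 5.696e+41

# a 190-clone sequencing batch simulated from the design, then QC'd
rep <- generate_repertoire(design, generator_config(seed = 42, n_clones = 190))
summarize_repertoire(rep$sequences, design)
#> <repertoire summary: 190 clones (178 usable VL, 103 usable VH)>
#>   residual template detected: 0 (0.00%)
#>   VH loop lengths: 5:3 6:2 7:7 8:2 9:2 10:6 11:8 12:9 13:12 14:8 15:8 ...

# library size from triplicate colony counts at 1e8 dilution
estimate_library_size(c(168, 175, 176), 1e8)
#> <library size: 1.73e+10 +/- 4.4e+08 (n = 3 replicates)>

# ELISA triage of a 50-clone plate with planted binders
fx <- generate_elisa_fixture(seed = 42)
call_hits(fx$plate)
#> <ELISA hits: 12 of 50 clones at >= 4-fold over control (mean = 0.0715)>
```

Reading the numbers: the theoretical table says the design's reservoir far
exceeds what any transformation can sample, so realized library size (the
colony-count estimate, here 1.73 × 10^10) is the binding constraint. The
repertoire summary shows full-length recovery of both CDR3s, the VH loop
length spread across the designed 5–28 range (usable VH counts drop with
length because the chance of a stop-free NNK run is (31/32)^k), and no
residual template. The hit caller returns exactly the wells at least
4-fold above the negative-control mean, ranked by fold.

A thin CLI over the same functions lives at `inst/cli/scfvlib.R`
(`design-stats`, `primer-qc`, `repertoire-qc`, `triage`, `synth`).

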