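---
title: "Designing and QC-ing a semisynthetic scFv CDR3 library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and QC-ing a semisynthetic scFv CDR3 library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfvlib)
```

## The problem

Semisynthetic antibody libraries concentrate their designed diversity in
the CDR3 loops, the main antigen-contacting regions, while keeping human
framework scaffolds. The loops are rebuilt by oligonucleotide-directed
(Kunkel) mutagenesis: degenerate primers anneal to a uracil-containing
single-stranded template, the heteroduplex is closed, and the
uracil-marked parental strand is degraded in an *ung+* host. The practical
questions this package answers sit on either side of that bench step: what
diversity does a degenerate-codon design actually encode; do the
mutagenesis oligos satisfy the arm-composition rules that keep parental
carryover low; can leftover parental plasmid be removed by restriction
digestion; does the sequenced library look like the design; and which
screening wells are worth carrying forward.

## Degenerate-codon algebra

Every degenerate position is an equimolar, independent mixture: one base
drawn uniformly from each IUPAC letter's base set. This equimolarity is an
assumption about oligo synthesis (hand-mixed or machine-mixed equimolar
phosphoramidites); codon-usage-biased mixes and trimer phosphoramidite
chemistry are out of scope. Under it, everything downstream is exact
combinatorics:

* `expand_codon()` enumerates the concrete codons; `aa_distribution()`
  pushes the uniform weight through the genetic code.
* Diversity products (`cassette_dna_diversity()`,
  `cassette_protein_diversity()`) are computed in exact
  arbitrary-precision integers (`big_integer`), because long NNK runs
  leave the exactly-representable double range (a 28-NNK cassette has
  $32^{28} \approx 1.4\times10^{42}$ DNA variants). The stop-free protein
  count factorizes over positions since positions are independent.
* Distribution sums are checked to within $10^{-12}$; the suite verifies
  all $15^3 = 3375$ degenerate codons against a brute-force enumeration
  that uses an independent IUPAC table and translator.

Two genetic-code modes are exposed and recorded in every report. The
default is the standard code (table 1). The `amber_suppressed` mode
translates TAG as Gln, because common display hosts such as *E. coli* TG1
are *supE* amber suppressors, so an NNK TAG is displayed as glutamine
rather than truncating the fusion. The standard code stays the default
since stop-free accounting is the conservative choice for diversity
claims; TAA/TGA remain stops in both modes.

## The cassette design

The shipped design targets a VH3–Vκ1 scFv scaffold.

**VL CDR3 (Kabat 91–96).** Position 91 is mostly tyrosine in natural
kappa light chains (roughly half) and 95 is a conserved proline, so two
primer variants are built: variant A fixes Tyr91, variant B randomizes 91.
Both share 92 = DRC, 93 = RRY (restricted, position-tailored diversity),
94 = NNK, fixed Pro95, 96 = NNK. The variants are pooled equimolar by
default, which yields ~50% Tyr at 91 plus the small Tyr mass of NNK —
close to the natural frequency. The codon used at 91 in variant B (NNK by
default) and the variant weights are configurable in `design_config()`,
because the exact primer-level choice is a genuinely open design point.

**VH CDR3.** The conserved Arg94–Asp101 salt bridge frames the loop, so
every cassette fixes those anchors and places $k$ NNK codons between
them, Kabat-labelled 95…100, then 100a…100z for long loops (supported up
to $k = 32$). Two sublibraries cover the natural length spread: S with
$k = 5\text{–}22$ and L with $k = 9\text{–}28$. Throughout the package,
"loop length" counts randomized residues only — the anchors are excluded —
and the sublibrary bounds are stated on that scale. Length cassettes are
pooled equimolar by default (mirroring equimolar primer pooling); a
length-weight vector can be supplied to the generator instead.

**Fixed codons.** Tyr→TAT, Pro→CCT, Arg→CGT, Asp→GAT, common human
codons; all configurable per design file. The constructor verifies that a
fixed position's codon expansion translates entirely to the declared
residue.

**Template and depletion sites.** The package ships a compact synthetic
template (not a natural V-gene; its frameworks are fixed synthetic
literals) whose VL CDR3 contains the unique SacI site GAGCTC and whose VH
CDR3 contains the unique NheI site GCTAGC. Digesting with both enzymes
cuts only unmutated parental plasmid, since mutagenized loops almost never
regenerate the sites: `cassette_site_regeneration_risk()` makes this
quantitative. Each window's match probability is an exact product (all
positions are independent draws); windows are combined as if independent,
which is exact when at most one window can match at all and an upper
approximation otherwise. A useful exact consequence: a run of NNK codons
can never contain GAGCTC or GCTAGC entirely within itself — in every
reading frame some site base falls on a K position that excludes it — so
regeneration risk comes only from windows overlapping the fixed arms.

## Primer QC

The arm-composition rules evaluated by `qc_primer()` are the ones that
matter for suppressing parental carryover during annealing: each
framework-complementary arm below 50% GC (strict), arm GC difference at
most 5 percentage points (boundary passes), and arm Tm within a window
around 45 °C. The Tm window is ±3 °C by default and configurable, since
"close to 45 °C" is a qualitative prescription. Rules are evaluated on
the unambiguous arms only; a degenerate core has no defined GC or Tm.

No single Tm convention is universal, so the method is explicit and
recorded in every report: the Wallace rule $2(A{+}T) + 4(G{+}C)$ for
arms up to 14 nt, and a two-state nearest-neighbor model with the unified
thermodynamic parameter set above that
($T_m = \Delta H / (\Delta S + R\ln(C_T/4))$, terminal initiation terms,
$0.368\,(N{-}1)\ln[\mathrm{Na^+}]$ entropy salt correction; defaults
500 nM strand, 50 mM Na⁺). The implementation reproduces independent
published-parameter calculations to well under 1 °C on the sequences
frozen in the test suite.

`equimolar_pool()` converts stock concentrations to volumes contributing
equal molar amounts (volume ∝ 1/concentration; with µM stocks, µL × µM =
pmol) and reports molecule counts via $N = c N_A v$.

## Repertoire QC

Clone reads are processed against the template with 12-nt framework
anchors flanking each CDR3 interval (0-based half-open coordinates
internally; Kabat labels only in reports). Each anchor is located exactly
first; only an anchor with no exact occurrence is re-sought with up to one
mismatch. This ordering matters: a long NNK loop occasionally contains a
near-copy of an anchor by chance, and without exact-first preference such
clones would be discarded as ambiguous even though their true anchors
match perfectly. A unique valid placement is still required at whichever
tolerance level is used; anything else is flagged `unanchored`.

Usability per region means extracted, in-frame, and stop-free
(stop-containing clones are counted but excluded from frequency matrices
by default — they cannot display; `include_stops` toggles this). VH
per-position counts are binned by Kabat insertion label across loop
lengths; because there is more than one defensible way to pool lengths, a
length-stratified set of matrices is available via `by_length = TRUE`.
Per-position Shannon entropy (bits) is 0 at fixed positions and at most
$\log_2 21$; logo matrices are row-normalized to 1 within $10^{-9}$.
Divergence from a user-supplied natural-repertoire reference is the
base-2 Jensen–Shannon divergence per shared position (0 for identical,
1 bit for disjoint support).

Residual template is called when an extracted CDR3 equals the template
CDR3 exactly or contains that region's depletion site; the evidence
string names the trigger. Site evidence can in principle fire on a mutant
that regenerated a site by chance — such clones would also be cut by the
depletion digest, so counting them as "template-susceptible" is the
operationally meaningful choice; the exact-match trigger remains
distinguishable in the evidence.

`estimate_library_size()` is plain serial-dilution arithmetic
(count × dilution / plated fraction per replicate, mean ± SD across
replicates).

## Screening triage

Panning enrichment is the per-round output/input titer ratio plus its
fold change between rounds. ELISA hits are wells at least `fold_threshold`
(default 4) times the negative-control summary; the summary is the
arithmetic mean by default (median optional) — the source protocols do
not say whether a mean or a single well is used, so the choice is
explicit. Equality at the boundary is a hit, calls are invariant to
common scaling of all absorbances, and ranking is by fold with
lexicographic id tie-break for determinism. Blank subtraction is off by
default.

## What the generator emulates — and what it does not

`generate_repertoire()` draws, per clone: template status
(`template_fraction`), a source (S/L/VL-only mix), a VH length (uniform
within the sublibrary unless weighted), a VL variant, then uniform
realizations of every degenerate position, embedded in the template
framework, with substitutions and then indels applied per base. One PRNG
stream per run, seed recorded in the outputs; identical configs produce
byte-identical FASTA/TSV.

Defaults mirror the study conditions the package models: 190 clones (one
sequencing batch), equimolar S/L, uniform lengths, zero template and zero
error. The ELISA fixture plants binders with lognormal low/high signal
components (controls near 0.08 absorbance units, binders near 1.0,
i.e. ~12-fold separation — a strongly separated plate like a successful
third-round screen); the panning fixture multiplies the recovery ratio by
a configurable factor per round.

The generator is deliberately composition-level. It does not model Kunkel
biochemistry (uracil incorporation, annealing kinetics), chromatogram
noise, synthesis bias across positions or lengths, clonal siblings from
amplification, or chimeric reads. Consequently, passing round-trip tests
demonstrates that the analysis code inverts the generative model exactly
— full extraction, exact length histograms, binomially consistent
template recovery — not that real Sanger data will be as clean; real
repertoires show length skews (the generator's `length_weights` exists to
emulate those once observed) and error modes the defaults do not produce.

## Numerical and scale choices

* Probability sums and JSD identities are asserted to $10^{-12}$; logo
  row sums to $10^{-9}$; pooling equality to $10^{-9}$ relative.
* Exact integer arithmetic (base-$10^4$ chunks) for diversity products;
  doubles only as convenience renderings.
* Deterministic tie-breaks everywhere a report orders items (fold, then
  id; Kabat numeric-then-insertion-letter order for positions).
* Degenerate inputs: empty repertoires summarize to zero counts; empty
  hit sets rank to empty tables; `n_clones = 0` generates empty outputs;
  zero-length sequences and missing arms error with typed conditions.
* Problem sizes in the shipped tests: full $15^3$ codon enumeration;
  cassette enumerations up to $10^5$ DNA variants; repertoires of 190 and
  10,000 clones (the latter for template-fraction recovery at the 11.1%
  spike rate, checked against the exact binomial 95% CI); 50-well ELISA
  plates. These sizes keep the whole suite around two minutes on one CPU
  while leaving the statistical checks well-powered.

## Known limitations

* The shipped template is synthetic; users with a real vector should load
  it via `read_template()` (FASTA + BED) and re-run
  `check_template_sites()` — arm/anchor uniqueness is a property of the
  template, not of the method.
* Site-regeneration risk treats overlapping windows as independent; for
  designs where several windows can complete a site simultaneously the
  value is an upper-bound-flavored approximation (exact per window).
* The natural-repertoire reference is user-supplied; no germline
  assignment or clonotype clustering is attempted.
* Indel-containing clones are flagged (`frameshift`) but not realigned;
  the package QCs, it does not error-correct.
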