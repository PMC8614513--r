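---
title: "Methods: branch-site scans for positively selected genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branch-site scans for positively selected genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`psgscan` detects protein-coding genes under episodic positive selection on
designated branches of a six-taxon primate tree and pushes the candidates
through the full downstream workflow: false-positive filtering, population
fixation of the selected codons, tissue-specificity comparison against
paralogs, and enrichment association tests. Ortholog inference, multiple
sequence alignment, alignment-confidence scoring, gene-family clustering and
cross-assembly liftover are all upstream of this package: their outputs
(CDS FASTA, protein alignments, column-score tables, family maps, VCFs on
the analysis assembly) are inputs here, and the synthetic-data module can
emulate each of them.

# The substitution model and the tests

Codon states are the 61 sense codons of the standard code. The
instantaneous rate from codon *i* to *j* is zero if they differ at more
than one nucleotide, and otherwise `pi_j * kappa^[transition] *
omega^[nonsynonymous]`; diagonals make rows sum to zero. The chain is
time-reversible, so `P(t) = exp(Qt)` is obtained from the symmetric
eigendecomposition of `D^{1/2} Q D^{-1/2}` with `D = diag(pi)`. Codon
frequencies default to F3x4 (position-specific nucleotide frequencies
estimated from the alignment, with a half-count to keep every sense codon
reachable); F1x4 and F61 are selectable.

The branch-site model mixes four site classes whose omega depends on
whether a branch is the foreground branch (classes 0, 1, 2a, 2b; omega1
fixed at 1; `p2a/p2b` derived from `p0, p1`). The test statistic is
`2(l_alt - l_null)` with the null pinning `omega2 = 1`, referred to the
upper tail of chi-squared with one degree of freedom. The plain chi-squared
reference (rather than the 50:50 point-mass mixture) is the package
default: it is the conservative convention in common branch-site practice,
and the type-I calibration test verifies the conservativeness empirically.

Selected sites are identified by Bayes empirical Bayes: the posterior
probability that a site belongs to class 2a or 2b, integrating
`(p0, p1, omega0, omega2)` over a discrete grid weighted by the full-data
likelihood at each grid point. The grid uses 10 points per dimension — a
triangular grid over the `(p0, p1)` simplex, omega0 uniform on (0, 1),
omega2 uniform on (1, 11) — with a uniform prior; kappa and the branch
lengths stay at their MLEs. Sites with posterior strictly above 0.95 are
called selected.

The selection-relaxation test is a deliberately simplified RELAX-style
model: three site classes `(omega0, 1, omega2)` shared by all branches,
with every class omega raised to a single power `K` on the test
(foreground) branches. `K` free versus `K = 1` is again a one-df LRT;
`K < 1` with `p < 0.05` flags relaxation. Outputs label it `relax_style`;
no compatibility with the external RELAX implementation is claimed.

# Numerical design

**Branch lengths and the rate scale.** Branch lengths are estimated once
per gene under M0 (single omega, all branches free) and held fixed for the
branch-site, null and relaxation fits — the usual dimensionality-stability
compromise. The substitution-rate normalisation of the mixture models is
likewise held at the M0 value, so branch lengths keep one fixed unit
(expected substitutions per codon under the M0 process) across all fits of
a gene. Holding the scale fixed makes the per-class site likelihoods
independent of the class proportions, which enables the profile
optimisation below; its only effect is the choice of branch-length unit,
since the lengths themselves are not refit.

**Optimisation.** All fits run in transformed space: log kappa, log branch
lengths, multinomial logit for `(p0, p1)`, logit for omega0, `log(omega2 -
1)` (upper bound 999, the conventional guard against divergence on
saturated data), log K in [0.02, 50]. The outer optimiser is L-BFGS-B with
relative log-likelihood tolerance ~1e-8, from small sets of deterministic
starting points (short exploration runs, then one polish from the best);
there is no random restarting anywhere, so every fit is reproducible
bit-for-bit. For the mixture models the class proportions are profiled
out at each outer point by an inner Nelder-Mead on the cached per-class
site likelihoods (the inner problem is two-dimensional and costs microseconds).
The inner optimiser is Nelder-Mead because R's L-BFGS-B implementation is
not reentrant.

**Missing data and degenerate input.** Gap codons (`---`) and codons
containing `N` are missing data: their conditional likelihood is summed
over states per sequence (column masking, never column deletion), so the
gap-proximity filter can still see per-sequence gap locations. An all-gap
column contributes log(1) = 0 and is flagged. Unconverged fits route the
gene to a skip list: it can never become a candidate, and an unconverged
relaxation fit passes that filter stage with a warning rather than silently
dropping the gene.

**Thresholds.** All cascade thresholds are strict inequalities — `p <
0.05`, BEB posterior `> 0.95`, column score `< 1.0` fails, gap within an
inclusive ±5-residue window fails, fixation frequency `> 0.95` — and every
one is a `scan_config()` field. The gap and score filters default to mode
`"any"` (one offending selected site removes the gene); mode `"all"` (the
gene survives while one clean site remains) is available because the
gene-level reading is also defensible. Gaps in any taxon count, not only
the foreground species, since an alignment error at a column corrupts all
rows.

# What the synthetic data emulates

`simulate_ortholog_set()` generates a complete, cross-referenced dataset:
per-gene CDS FASTA for the six taxa, protein alignments, column scores,
the marked species tree, single-exon GFF3 gene models, a VCF of population
variants with allele frequencies, a genes-by-tissues TPM matrix, a family
map with truncated-geometric family sizes, a disease-gene list, and a truth
table recording which genes were simulated under selection and where.
All randomness flows from one integer seed through named sub-streams, so
each stage reproduces independently and identical seeds give byte-identical
files.

Alignments evolve under the branch-site process itself: each site draws a
class, the root codon comes from the equilibrium distribution, and codons
evolve along each branch with the class- and branch-appropriate omega.
Branch lengths are interpreted on the background-mixture scale, so the
foreground branch genuinely accumulates excess nonsynonymous change for
class-2 sites.

The default study conditions were fixed after a pilot power analysis and
then frozen: tree

```
((((hsap:0.25, ptro:0.25)Hominini:0.08, ggor:0.18)Homininae:0.08,
   pabe:0.25)Hominidae:0.12, nleu:0.35, mmul:0.45)
```

(branch lengths in expected codon substitutions — several-fold longer than
real great-ape divergences, deliberately, so that 300-codon genes carry
measurable signal), site-class mix `p0 = 0.7, p1 = 0.2` (p2 = 0.1),
`kappa = 2.5`, `omega0 = 0.1`, selected-class `omega2 = 8` for genes
flagged as PSGs and 1 otherwise, column scores exactly 1.0 unless a low
fraction is requested, and planted fixation flags with probability 0.8.
Under these conditions the pilot gave branch-site LRT power ~0.9 at
alpha = 0.05 and a null rejection rate well under 0.05.

What the generator does **not** emulate: indel evolution (gaps are injected
mechanically, not evolved), real demography or linkage in the variant
tables, the perturbation algorithm behind real alignment-confidence scores
(scores are sampled), isoform structure (one CDS per gene, single exon in
generated models — though the coordinate mapper itself supports multi-exon
and reverse-strand genes), and real tissue atlases. Passing tests therefore
demonstrate the correctness and calibration of the machinery under the
model's own assumptions, not robustness to alignment error or demographic
structure in real data.

# Interpretation conventions

Coordinates are 1-based inclusive everywhere (alignment columns, per-taxon
ungapped residue positions, genomic positions); reverse-strand codons are
reported as their three genomic positions in ascending order with a strand
flag, which makes VCF overlap strand-agnostic. "These alleles" in the
fixation rule is read as the allele carried by the analysis assembly at
each codon position — the only allele identifiable without phasing; with
frequency data a site is fixed when every overlapping variant leaves that
allele above 0.95, without frequency data when no alternative allele
segregates in the codon. Indels and multi-nucleotide variants overlapping
the codon count as segregating. A gene is fixed when at least one of its
selected sites is.

The association tests are one-sided upper-tail Fisher exact tests
(exact hypergeometric summation, verified against brute-force enumeration):
this is the direction consistent with the published tables the package
replicates, including the depleted cell that yields a large p-value.
Proportions are reported rounded half-up to three decimals with the raw
values retained. No multiple-testing correction is applied across the
seven branch tests per gene; that is deliberate fidelity to the workflow
being reimplemented.

Seven foreground labelings are tested per gene — the four terminal great-ape
branches and the Hominini, Homininae and Hominidae stem branches — each as
an independent test. "Hominidae" means the great-ape stem branch only, not
all great-ape branches jointly.

# Problem sizes

The test suite validates the likelihood engine against exhaustive
enumeration on 3-taxon, 3-codon instances; calibrates the branch-site LRT
on 200 null simulations (300 codons) and its power on 50 simulations at
omega2 = 8; checks BEB site ranking on 20 replicates at omega2 = 10;
calibrates the relaxation test on 100 null replicates; and runs the full
pipeline on a 20-gene, 300-codon planted dataset. These sizes are the
package's chosen compromise between statistical resolution and a test
suite that completes in well under an hour on a single core; the
acceptance script uses moderately smaller replicate counts for the same
quantities.

# Known limitations

* Estimates of omega2 are noisy at desk scale; the calibration targets are
  rejection rates and rankings, not parameter recovery to high precision.
* The RELAX-style test shares its three classes across branches; genes with
  genuinely branch-variable class structure are outside its model space.
* The BEB grid caps omega2 at 11; sites evolved far above that remain
  detectable but their posterior is driven by the top grid cell.
* The fixation caller attributes summed ALT frequencies conservatively for
  multiallelic records (a multiallelic assembly-ALT site is never called
  fixed).
* With branch lengths fixed from M0, part of a strong foreground signal is
  absorbed into the foreground branch length before the branch-site fit
  sees it; this depresses power on short branches and is the main reason
  the simulation defaults use stretched branches.
* The relaxation filter interacts with strong foreground selection: under
  the single-K shared-class model, concentrated positive selection on the
  test branch is often best fit as K < 1 (the K > 1 route would force
  foreground hyper-conservation at the conserved class through the same
  exponent), so the literal exclusion rule (K < 1 and p < 0.05) can remove
  genuinely selected genes when the effect is strong. On the synthetic
  datasets this is visible as final-PSG counts well below candidate
  counts; the planted-recovery checks therefore anchor on the candidate
  stage, where detectability is governed by the branch-site test itself.
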