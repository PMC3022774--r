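---
title: "Molecular forensics of a plant mitochondrial horizontal gene transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular forensics of a plant mitochondrial horizontal gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenotract)
```

## The problem

When a parasitic plant and its host exchange mitochondrial DNA, the
recipient genome can end up carrying two homologs of the same gene: the
native copy and a horizontally acquired *xenolog*. Establishing that a
candidate copy really is foreign — and reconstructing what happened to it
afterwards — is a chain of inferences, each with its own statistical
machinery:

1. **Is the copy foreign?** A foreign copy places phylogenetically inside
   the donor clade, far from the native homologs, with strong bootstrap
   support. The mundane alternative — an ancient gene duplication inside
   the recipient family — predicts the extra copy sister to the native
   clade, and can be rejected with a likelihood-based topology test.
2. **Did the copies recombine?** Co-resident xenologs can overwrite each
   other by gene conversion. Converted segments show up as runs of
   informative sites at which the putative recombinant matches the native
   homolog rather than the donor lineage.
3. **Was the transfer DNA- or RNA-mediated?** Plant mitochondrial
   transcripts undergo C-to-U RNA editing. A transfer that passed through an
   edited transcript (cDNA) carries `T` at ancestral edit sites; a genomic
   DNA transfer retains `C`.
4. **How degraded is the foreign copy?** Frameshifting indels and premature
   stop codons mark pseudogenization; synonymous/non-synonymous divergence
   (dN/dS) quantifies how fast the copies have been evolving and under what
   constraint.
5. **Where does the foreign copy live?** The mitochondrial, plastid and
   nuclear genomes differ enormously in copies per cell, so qPCR threshold
   cycles across differentially enriched DNA fractions localize an
   unexpressed locus to a compartment.

`xenotract` implements this entire chain as composable functions plus a
synthetic-data generator that simulates the full study design with a
ground-truth ledger, so every stage can be validated end to end without any
external data.

## Models and procedures

### Phylogenetic engine

Likelihoods use GTR+Γ+I: a general time-reversible rate matrix scaled to
one expected substitution per site, discrete-Gamma rate heterogeneity with
equal-probability categories represented by their means (4 categories by
default), and a proportion of invariant sites; with invariant proportion
$p_{inv}$ the Gamma rates are rescaled by $1/(1-p_{inv})$ so branch lengths
stay in substitutions per site. `log_likelihood()` is an in-package
Felsenstein pruning implementation that returns per-site log-likelihoods —
these feed the topology tests — and is checked in the test suite both
against exhaustive summation over internal-node states and against an
independent likelihood engine.

Tree search (`ml_search()`) is nearest-neighbor-interchange hill climbing
with interleaved branch-length and model-parameter optimization, run from a
neighbor-joining start plus randomized-NNI restarts (5 by default). NNI
with restarts replaces full SPR searching deliberately: the trees in this
problem have at most a few dozen leaves, where NNI restarts reliably find
the same optimum at a fraction of the cost. Base frequencies default to
empirical counts, with ML estimation as an option. Bootstrap support
resamples columns and re-searches each replicate from the ML topology with
model parameters fixed — the standard reduced-effort bootstrap.

`topology_test()` implements both the Shimodaira–Hasegawa test (RELL
resampling with per-tree centering and the max-step statistic, so the best
tree has p = 1 by construction) and the approximately unbiased test
(multiscale RELL at scales 0.5–1.4× the site count, 1000 draws per scale,
weighted-least-squares fit of $q_{norm}(1-bp)$ to
$d\sqrt{r} + c/\sqrt{r}$, $p_{AU} = 1 - \Phi(d - c)$). The SH test is used
for the duplication-versus-transfer constraint; the AU test confirms long
conversion tracts.

### Copy classification

`classify_copies()` roots the bootstrapped ML tree at the outgroup and
locates the donor clade (the smallest clade containing every donor
reference). A query is **foreign** if it is nested inside that clade and
**native** otherwise; either call requires the donor-group bipartition to
reach 80% bootstrap support (the conventional display threshold for strong
support), else the record stays **unknown**. The duplication alternative is
built by moving the foreign-called records — as a unit, keeping their
observed internal structure, since their within-clade relationships are
often non-monophyletic by line and the constraint should not invent
resolution — to be sister to the native recipient clade, then comparing
against the ML tree with the SH test.

### Conversion tracts

`extract_informative_sites()` reduces a (query, donor reference, native
homolog) triplet to a binary string over the columns where the parents
differ and the query matches exactly one of them; query autapomorphies are
excluded, so a private substitution inside a tract does not interrupt it.
The run statistic is the length of a maximal run of consecutive
native-matching sites (strict runs, which is how reported tracts are
delimited in practice). Significance comes from shuffling the site labels
over their positions (10,000 permutations; p-values use the add-one
continuity correction, so the smallest attainable p is
$1/(B+1)$); the run test applies the null distribution of the *maximal*
run, exact for the longest run and conservative for secondary ones. Tract
coordinates are reported from the first to the last supporting informative
site, inclusive, in original alignment columns — so a tract's length counts
alignment columns, and the ground truth the generator records uses the same
informative-site-delimited convention. Tracts longer than 100 nt must
additionally survive `confirm_long_tract()`: the alignment is split into
tract and remainder, each region gets its own ML tree, and the tract region
must reject the remainder's topology in the AU test at p < 0.05.

### Edit sites and transfer mechanism

`predict_edit_sites()` is a conservation-based predictor: a target `C`
homologous to known edit sites is scored by the fraction of assessable
reference sequences whose *edited* codon encodes the same amino acid as the
target's hypothetical post-edit codon; the prediction threshold is 0.2.
This reduces the published prediction criterion ("the edit restores the
conserved protein") to its alignment-context form. Sites where the target
lacks `C` are never predicted. `tally_retention()` counts C/T at the
homologous sites in a foreign copy, and `classify_mechanism()` compares the
thymidine count against two binomials: RNA-mediated (edited fraction,
default 0.9 — most edit sites are found fully edited in transcript surveys)
and DNA-mediated (background C-to-T substitution). The verdict is the model
that survives rejection at 0.05; when a single gene offers only a handful
of sites, the pipeline also pools sites across genes per foreign copy,
which is how a 20-something-site tally across three genes becomes decisive.

### Divergence

`pairwise_dnds()` follows the counting conventions appropriate for
pseudogene/native contrasts: Nei–Gojobori sites and pathway-averaged
differences (mutations to stop codons count as non-synonymous sites, so
S + N = 3 per codon; pathways through stops are excluded; codons containing
a stop, gap or `N` in either sequence are dropped pairwise), Jukes–Cantor
correction for multiple hits, recoding of predicted edit-site columns to
`T` in both sequences *before* counting, removal of codons overlapping
detected conversion tracts, and codon-resampling bootstrap standard errors
(500 replicates). ω is reported as dN/dS whenever dS > 0. Frame restoration
(`restore_reading_frame()`) makes these statistics computable on
pseudogenes: frameshifting insertions relative to a functional reference
are masked to `N` (never deleted, preserving column coordinates) and
deletions are logged as compensating gaps, leaving the reference frame as
the codon coordinate system.

### Compartment localization

`classify_compartment()` formalizes the qualitative "which curves travel
together" reading of qPCR amplification plots: mean Ct profiles over the
three fractions (total, mitochondria-enriched, plastid-enriched) are
centered within each fraction — making calls invariant to fraction-wide
offsets such as template amounts — and the query is assigned to the nearest
compartment marker profile by weighted mean absolute Ct difference. The
plastid-enriched fraction carries double weight because it provides the
greatest three-genome separation. Calls need a 2-cycle margin over the
runner-up; otherwise the result is `ambiguous`. Duplicates are averaged
after a 1-cycle spread check.

## The synthetic-data generator

`simulate_dataset()` emulates the study design that motivates the package:

* a species tree with a donor clade of four species, a recipient clade of
  three, and two outgroups (12 sequences per gene once the three foreign
  copies are added);
* three genes at realistic plant-mitochondrial lengths (424, 205 and 626
  codons) carrying 1, 15 and 10 C-to-U edit sites respectively (26 total);
* codon sequences evolved by a GTR nucleotide process with ω-dependent
  acceptance of non-synonymous proposals (functional copies ω = 0.2, stops
  rejected) rather than a full 61×61 codon matrix — sufficient to generate
  the dN/dS contrasts being tested and much easier to verify;
* one horizontal transfer from the donor lineage into the recipient clade
  ancestor; the transferred copy then evolves as a pseudogene (ω = 1, stops
  allowed, rate multiplier 40, frameshift-biased deletions with geometric
  lengths around 2);
* edit sites held at genomic `C` in functional lineages (placed at codon
  position 2, where a C-to-U edit is always non-synonymous — a
  conservation-score predictor cannot flag synonymous third-position edits,
  so simulating them would only create undetectable truth); the transfer
  mechanism sets the foreign copies' edit-site states (`DNA`: `C` with 2%
  background C-to-T per tip; `RNA`: `T` at the 0.9 fully-edited fraction);
* a default native-partner conversion tract implanted in the atp1-like
  gene, with the realized informative-site span recorded as observable
  truth;
* a qPCR panel built from copies per cell (nucleus 2, mitochondrion 50,
  plastid 500), enrichment factors (mitochondrial ×20 in its fraction,
  plastid ×10 in its fraction), perfect efficiency and Gaussian Ct noise
  (sd 0.3 cycles).

Branch lengths were set once so the generated data reproduce the study's
headline structure: native copies in the recipient clade are >99%
identical, foreign copies are in the mid-80s% identical to each other and
to the donor lineage, and the foreign:native synonymous-divergence ratio on
the three-gene concatenation lands in the reported 15–25× band. Deletions
are placed away from edit sites and tract spans, so every configured tract
is realizable and the run is fully deterministic under its seed (the same
guarantee a regenerate-on-collision scheme would give, without the retry).

What the generator does **not** emulate: alignment error (sequences are
generated aligned; insertions are produced only by the frame-restoration
test fixtures, not the generator), within-species line structure beyond a
metadata field, rate variation along the genome other than discrete-Gamma,
substoichiometric genome forms, and nuclear integrations. Passing tests on
this generator therefore validate the statistical machinery under the
assumed generative model — they do not certify performance on real
alignments with alignment artifacts or more tangled histories.

## Numerical choices

* Branch lengths are bounded to [1e-8, 10]; NJ branch estimates below zero
  are clamped to zero; saturated distances are capped at 1.5× the largest
  finite distance with a warning.
* Likelihood pruning rescales partials per node and per pattern; the
  mixture over rate categories is combined on the log scale.
* All stochastic operations (search restarts, bootstrap, RELL, permutation,
  simulation) take explicit seeds and default to seed 1; identical seeds
  give byte-identical outputs.
* Permutation p-values use (1 + exceedances)/(B + 1); a warning is issued
  when B < 1/α.
* IUPAC ambiguity codes other than `N` are mapped to `N` on input with a
  warning; `N` and gaps are excluded by pairwise deletion everywhere.
* Coordinates are 1-based and inclusive everywhere, including tract ranges
  and kept-column maps.
* Block filtering uses a single-tier conserved-column criterion (majority
  residue ≥ b2 among non-gap residues) with the relaxed defaults b2 = 50%,
  minimum block 5, maximum gap fraction 50%; this simplifies the two-tier
  scheme of the original block-filtering program, which the relaxed
  settings make essentially binary anyway. Filtering is applied after
  foreign pseudogenes are added, with the column map making the choice
  auditable.

## Validation scale

The repository's test suite and `scripts/acceptance.R` validate the
pipeline at these problem sizes, chosen to give stable proportions while
keeping a full run in minutes on one core: 1000 codon pairs and five
4-taxon × 10-site alignments against exhaustive oracles; 2000 null triplets
(900 nt, 10% parent divergence) for permutation calibration; 100 implanted
tracts (1500 nt, 300-column implant, ≥15 informative sites) for recovery;
200 simulated transfers at 20 edit sites for mechanism accuracy; 50
simulated datasets — classification exercised on the atp1-like gene of
each, 20 bootstrap replicates, 2 search restarts — for foreign-copy
precision/recall and duplication rejection; 100 replicates each at true
dS ∈ {0.02, 0.1, 0.3} on 5000 codons for estimator bias; and 100 qPCR
panels for compartment-call accuracy.

## Known limitations

* The SH/AU machinery evaluates the candidate trees it is given; it does
  not search constraint space. Pathological constrained trees (e.g. a
  foreign group that is wildly non-monophyletic) fall back conservatively.
* The conversion scan is a triplet method: it needs a sensible donor
  reference and native partner and reports nearest-partner evidence only —
  it never claims which molecular route produced a tract.
* PREP-style prediction inherits the blindness of conservation scores to
  synonymous edits.
* The NG estimator saturates near p = 3/4; saturated bootstrap replicates
  are dropped from SE computation, and saturated point estimates raise an
  error rather than returning a number.
* classify_compartment assumes markers behave (efficiencies near 1,
  enrichment monotone); it will happily report `ambiguous` rather than
  guess when profiles collapse.
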