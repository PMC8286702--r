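---
title: "Characterizing a plant aquaporin (MIP) gene family with mipfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a plant aquaporin (MIP) gene family with mipfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipfam)
```

## The problem

Aquaporins (major intrinsic proteins, MIPs) are channel proteins that move
water and small solutes across membranes. In plants they fall into five
subfamilies — PIP, TIP, NIP, SIP and XIP — distinguished by sequence,
subcellular target and substrate range. A genome-wide family
characterization answers a standard battery of questions: which genes in a
genome are aquaporins; what are their physicochemical and structural
properties; how do they partition into subfamilies; how did the family
expand (tandem vs segmental duplication, under what selection pressure,
and when); and which members' expression tracks a phenotype of interest —
here, water accumulation in a developing fruit tissue such as the juicy
outer seed coat of pomegranate.

`mipfam` implements that battery as composable, tested R functions, and
pairs every analysis stage with a deterministic synthetic-data generator
that emits truth labels, so the whole pipeline can be exercised and
validated without downloading a genome.

## Candidate identification

`homology_screen()` compares each protein of a proteome against reference
aquaporin queries. A candidate is accepted when

* query coverage > 0.5 — read as the fraction of the *reference* covered
  by the alignment, not percent identity (identity is reported but not
  filtered on),
* e-value < 0.01,
* at least 4 predicted transmembrane segments (family members with 4–7
  segments are known), and
* at least one NPA-type motif.

Two modes exist. `import` filters a standard 12-column tabular hit file.
`builtin` runs Smith–Waterman locally (BLOSUM62, gap open 10, extend 0.5)
and converts raw scores to approximate e-values with ungapped
Karlin–Altschul statistics ($\lambda = 0.318$, $K = 0.13$) over the
effective search space $m \times n$. The builtin statistic is an
approximation of a database-search e-value; it is monotone in the score,
which is what the accept/reject rule needs, and the import mode exists for
exact fidelity to an external search. Each protein receives at most one
call: best e-value, ties broken by higher score, then lexicographic
reference id.

## Physicochemical profile

* **Molecular weight**: sum of average (not monoisotopic) residue masses
  plus one water, in kDa — matching the behavior of the standard web
  calculators used in this field.
* **Isoelectric point**: bisection on the Henderson–Hasselbalch net-charge
  function over D, E, C, Y, H, K, R and the termini, with the
  Bjellqvist pKa set (residue-specific N-terminal pKa). Bisection stops at
  $|Q| < 10^{-4}$; the suite verifies the residual is below $10^{-3}$
  on random proteins.
* **GRAVY**: the mean Kyte–Doolittle index; positive for membrane
  proteins.
* **Transmembrane segments**: a 19-residue sliding Kyte–Doolittle window;
  a window centre qualifies above mean hydropathy 1.6; runs of qualifying
  centres closer than 5 residues are merged and runs shorter than 15
  residues are dropped. These are the classic recommendation values. This
  hydropathy scan deliberately replaces HMM-based topology predictors
  (web services, out of scope here); counts on real proteomes can differ
  from published HMM counts, and the profile records the method.

## Alignment, phylogeny and subfamily naming

`progressive_align()` is a minimal deterministic progressive aligner:
3-mer distances feed a UPGMA guide tree, profiles are merged by
profile–profile Needleman–Wunsch (BLOSUM62, affine 10/0.5). For two
sequences it reproduces the reference pairwise implementation score
exactly (tested). Externally aligned FASTA can be imported instead and is
validated against the same invariants.

Distances are p-distances with pairwise deletion (a common default for
protein NJ when nothing else is stated); a Poisson correction
$-\ln(1-p)$ is available behind a flag. `neighbor_joining()` is the
Saitou–Nei algorithm with two determinism rules: the joined pair is the Q
minimizer with ties broken by smallest index pair, and negative branch
lengths are clamped to zero with the deficit moved to the sibling branch
so path lengths through the new node are preserved. On additive matrices
NJ is exact — the suite checks exact topology and path-length recovery on
random trees up to 8 taxa. `bootstrap_supports()` resamples alignment
columns with replacement, rebuilds NJ per replicate, and reports the
percentage of replicates containing each original bipartition;
1000 replicates is the conventional setting, and the computation is fully
seed-deterministic.

`assign_subfamilies()` gives each candidate the subfamily/subgroup of its
highest-identity labeled reference (global-alignment identity over aligned
length). Candidates below 25% identity to every reference stay
unclassified; when the two best references disagree on subfamily within 1
percentage point the call is flagged ambiguous and, if a tree over
candidates and references is supplied, resolved by smallest patristic
distance. Names are `<prefix><subgroup>.<rank>` with ranks by descending
identity — mirroring the field convention of naming new members after
their closest characterized homolog.

## Conserved residues

`scan_npa()` reports Asn-Pro-X triplets with X in the naturally observed
variant set (A, S, T, V, G, C, L, I, M); the canonical motif has X = A,
NIP-like members typically carry NPS in loop B and some SIPs carry NPT.
`extract_filter_residues()` formalizes what is usually done by eye on a
multiple alignment: the target is globally aligned to a curated anchor
whose NPA, ar/R selectivity-filter (H2, H5, LE1, LE2) and Froger (P1–P5)
positions are annotated, and the target residues opposite those positions
are reported verbatim (gap marks where the target has none). Extraction
refuses targets under 20% identity to the anchor. The suite proves the
operation is the identity on anchors, recovers planted point mutations at
annotated positions exactly, and is untouched by off-site mutations at a
10% load.

The bundled anchors are synthetic consensus-like scaffolds, one per
subfamily — six strongly hydrophobic 23-residue blocks, loops with the
NPA pair, subfamily-typical filter residues — not database records. They
make the machinery testable offline; for real analyses, supply curated
anchors from a reference species.

## Duplication, Ka/Ks and dating

Duplicate pairs are protein pairs with global identity ≥ 40% and coverage
(fraction of the shorter protein in gapless aligned columns) ≥ 0.75. A
pair is **tandem** when both genes share a chromosome, their
nearest-boundary separation is at most 100 kb and coverage is at least
0.75; otherwise **segmental** when the pair anchors a collinear block;
otherwise dispersed. `detect_collinear_blocks()` is a simplified
MCScanX-style chainer: homologous pairs become dots in gene-rank space per
chromosome pair and the longest same- or inverted-orientation chains with
rank gaps ≤ 25 on both axes are reported when they carry ≥ 5 anchors
(the MCScanX default scale).

`ng86_kaks()` implements Nei–Gojobori (1986) counting:

* per codon position, the synonymous site fraction is the share of the 3
  possible nucleotide changes that preserve the amino acid; changes to
  stop codons count as nonsynonymous sites,
* $S$ is averaged over the two sequences and $N = 3L - S$,
* codon pairs differing at $k$ positions average their synonymous /
  nonsynonymous step counts over all $k!$ single-step pathways, excluding
  pathways through stop codons (if every pathway crosses a stop, all are
  kept — a documented fallback),
* proportions are Jukes–Cantor corrected,
  $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, undefined at $p \ge 0.75$;
  the result is flagged invalid there and at $K_s = 0$.

The implementation is tested for exact equality against a brute-force
pathway-enumeration oracle on hundreds of random short codon pairs, and
for parameter recovery (within 15% mean relative error) on 300-codon pairs
simulated at planted rates.

Divergence time uses $T = K_s / 2R$ with $R = 1.5\times10^{-8}$
synonymous substitutions per site per year, a standard dicot rate. The
literature on this family also prints times computed as $K_s/0.3$ —
numerically the same formula with the $10^{-8}$ scale dropped, hence 10×
smaller values; `divergence_time()` returns both (`time_mya` strict,
`time_mya_alt` for comparability with such tables). Selection calls are
the textbook rule: $K_a/K_s < 1$ purifying, $= 1$ (within $10^{-9}$)
neutral, $> 1$ positive.

## Expression and water accumulation

* `log2_transform()`: $\log_2(\mathrm{FPKM} + 1)$; the pseudocount is
  unavoidable with zeros present and is recorded on the output.
* `water_content()`: $(FW - DW)/FW \times 100$.
* `ddct_fold_change()`: the $2^{-\Delta\Delta C_t}$ method with
  $\Delta C_t$ averaged over biological replicates (a per-replicate
  variant is available behind a flag), standard errors over replicates.
* `expression_water_regression()`: ordinary least squares plus Pearson r
  with the two-sided t-test $t = r\sqrt{(n-2)/(1-r^2)}$; zero-variance
  series are flagged undefined rather than producing spurious values.
* `anova_tukey()`: one-way ANOVA with Tukey HSD (via the studentized-range
  distribution in base R) and a compact letter display computed
  in-package. Pairing of expression and water observations is taken from
  the input tables, never guessed.
* `candidate_selection()`: genes with a significant positive regression
  *and* mean expression above an FPKM threshold in the designated
  late-stage target-tissue samples, ranked by r — the rule that singles
  out water-accumulation candidates.

## What the generators emulate — and what they do not

`simulate_genome()` builds a toy genome whose defaults mirror a small
dicot aquaporin complement: 38 members split 14/13/8/2/1 over
TIP/PIP/NIP/SIP/XIP on 8 chromosomes, one tandem pair, seven segmental
pairs inside collinear blocks, plus unrelated decoys. Members derive from
the bundled scaffolds by topology-aware substitution: membrane blocks
mutate within strongly hydrophobic residues, loops within hydrophilic
ones, and annotated motif positions never change — so divergence never
destroys the structural signal the screen relies on. Exon counts echo the
conserved family gene models (TIPs 3 exons, PIPs 4). Duplicate partners
are created at 8% protein divergence with extra synonymous codon swaps,
planting a clear $K_s > K_a$ (purifying) signal.

Two design choices deserve emphasis:

* **Within-subfamily divergence defaults to 0.40–0.45**, with members
  redrawn until every non-partner pair sits below 38% identity. This makes
  "detected duplicate pair" and "planted duplicate pair" coincide exactly
  under the 40% pair threshold, which is what closed-loop tests need. Real
  subfamilies are more conserved (plant PIPs commonly exceed 70% mutual
  identity), so on real data the pair list is a superset that the
  collinearity and tandem rules then classify — passing tests here shows
  the rules are implemented correctly, not that real pair lists are this
  clean.
* **The codon-pair generator refuses targets ≥ 0.75 substitutions/site**
  ("saturation"): beyond that the Jukes–Cantor proportion approaches its
  domain boundary and recovery is unreliable, so the generator treats such
  targets as out of its regime rather than producing data no estimator
  should be trusted on.

`simulate_expression()` plants: tissue/stage-structured FPKM with
negative-binomial noise; an outer-seed-coat water series rising over
development; correlated genes whose expression tracks water linearly with
noise calibrated to a target Pearson r (default 0.9); and Ct tables
encoding known fold changes against a constant reference gene. It does
not model library-size effects, gene length bias, batch structure or
count-level mean–variance trends, so passing tests demonstrate estimator
correctness, not robustness to real RNA-seq artifacts.

## Numerical choices

* Coordinates are 1-based inclusive throughout (GFF3 convention); the
  representative isoform is the longest CDS.
* Stop codons: one terminal stop is stripped before translation
  comparison; internal stops flag a locus invalid (warning, not error).
* Alignment parameters are fixed (BLOSUM62, open 10, extend 0.5) across
  all modules so identities and coverages are comparable.
* All stochastic steps (bootstrap, generators) consume explicit seeds and
  restore nothing global they do not own; repeated runs are byte-identical.
* Problem sizes in the shipped tests and acceptance script are chosen at
  desk scale: genomes of ~30–60 genes, alignments of 4–8 taxa for exact
  NJ checks, 300-codon pairs over 20–50 seeds, 200 null expression seeds.
  These sizes give tight closed loops while keeping the whole suite in the
  order of a minute per file.

## Known limitations

* The builtin e-value is an ungapped approximation; ranking is faithful,
  absolute values are not database-calibrated.
* The hydropathy TM scan is not an HMM; proteins with marginal or broken
  helices may count differently than topology predictors report.
* The progressive aligner is adequate for closely related family members;
  for deep or gappy alignments import an external MSA.
* NJ with p-distances is the method historically used for such family
  trees, not the best available phylogenetic estimate.
* The collinearity chainer handles single-scale blocks; it does not model
  block merging, transposed duplicates or WGD-aware classification.
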