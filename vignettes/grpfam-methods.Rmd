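---
title: "Methods: comparative analysis of RB-GRP gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of RB-GRP gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grpfam)
```

# Scope and model

grpfam implements a complete comparative gene-family workflow for
RNA-binding glycine-rich proteins (RB-GRPs), the fourth class of the plant
glycine-rich protein superfamily. The workflow has five analytic stages —
family identification, genome context, distance-based phylogenetics,
duplication and selection analysis, and qPCR expression — plus a seeded
synthetic-data generator that plants known truth for every stage. Each
stage is a set of data-frame-first functions returning tibbles, so whole
analyses compose with the pipe.

# Family identification

A protein joins the family when three independent lines of evidence agree:

1. **Domain evidence.** A per-domain hit table (the HMMER domtblout
   dialect) is filtered at a full-sequence E-value strictly below `1e-4`.
   At least one hit must map to an RNA-recognition motif (RRM) or
   cold-shock domain (CSD) profile. Two E-values are used deliberately:
   the full-sequence value gates family inclusion, while the per-domain
   independent value gates which hits become architecture tokens — the
   domtblout format carries both, and using the independent value for
   tokens avoids promoting marginal secondary domains on the strength of
   an unrelated strong hit.
2. **Glycine richness.** A window of 20 residues slides by one; the
   protein passes if some window holds strictly more than 50% glycine,
   i.e. at least 11 of 20. The strict inequality follows the "more than
   50%" phrasing of the criterion. Sequences shorter than the window are
   scored on their full length, so short proteins are not auto-rejected.
3. **Architecture.** Surviving hits are ordered by envelope start;
   same-class hits with reciprocal overlap above 50% of the shorter
   envelope are merged, so repeated weak hits on one domain are never
   double-counted as two RRMs.

Subfamily classification is a pure function of the ordered token list,
with precedence CSD first:

| Architecture | Class |
|---|---|
| any CSD (with or without zinc fingers) | IVc |
| two or more RRMs | IVd |
| one RRM + zinc finger(s) (CCHC or RanBP2 type) | IVb |
| one RRM | IVa |
| anything else | UNCLASSIFIED |

Two classification choices deserve comment. First, a CSD with a *single*
CCHC zinc finger classifies as IVc even though the textbook definition
asks for two or more zinc fingers: observed family tables contain
CSD-C2HC rows labelled IVc, and we follow the observed assignments.
Second, RanBP2-type zinc fingers count toward IVb, again following
observed RRM-RanBP2-RanBP2 rows. Reported family tables occasionally
assign a lone RRM to IVb; such rows are inconsistent with the definitions
and with every other row, and this package classifies a lone RRM as IVa.

Non-redundancy is the longest translated isoform per gene locus, ties
broken by protein id. Molecular weight uses average (not monoisotopic)
residue masses plus one water, in kDa; isoelectric point solves the
Henderson–Hasselbalch net-charge equation under the Bjellqvist pKa set
(the set behind the common web calculators) by bisection on pH 0–14 to a
charge tolerance of `1e-4`. `X` residues are an error by default;
`allow_x = TRUE` assigns the mean residue mass and no charge.

# Genome context

Gene models come from GFF3 (1-based inclusive coordinates). We keep the
1-based inclusive convention internally because every container the
package builds on (GFF3 itself, the Bioconductor ranges ecosystem) uses
it; converting to a half-open convention at the boundary would buy nothing
and invite off-by-one errors. Exons are taken from the longest mRNA
(summed exon length), consistent with the longest-isoform rule.

Gene *rank* — the 1-based position in the start-coordinate order of a
chromosome, ties broken lexicographically by gene id — is the substrate of
the duplication rules. Strand is ignored by ranking; only physical order
matters. "Linked" family pairs default to a rank gap of at most 10; the
underlying studies report linked pairs without stating a criterion, so the
gap is exposed as a parameter (set it to 1 for strict adjacency) and the
default is a stand-in, not a claim of equivalence.

# Phylogenetics

Distances use pairwise deletion (sites with `-` or `X` in either row are
dropped per pair; `X` is treated as a gap because it carries no
comparable residue information) and either the raw p-distance or the
Poisson correction `d = -ln(1 - p)`, which linearizes an equal-rate,
equal-exchange substitution process. Saturated pairs (`p >= 1`) and pairs
with zero comparable sites are errors, not silent zeros.

Neighbor-joining is implemented from the Saitou–Nei Q-criterion with two
determinism guarantees the classical description leaves open: ties in Q
are broken by the lexicographically smallest pair of cluster labels, and
negative branch-length estimates are clamped to zero with the clamped
amount transferred to the sibling edge (the common behavior of
distance-matrix software). The alignment itself is an input — any multiple
alignment in FASTA works; the package does not re-implement profile
alignment.

Bootstrap resamples alignment columns with replacement at the original
length, rebuilds the tree per replicate, and scores each internal edge by
the percentage of replicates containing the same leaf bipartition, rounded
to the nearest integer. Replicates on which a distance is undefined are
redrawn and counted. The default is 1,000 replicates; the test-suite and
the examples below use 100–200, a deliberate scale-down that leaves the
support estimator unchanged. Edges at or below 50% support are collapsed
("higher than 50%" is read strictly), producing polytomies; contraction
discards the contracted edge's length and keeps the children's.

Domain segments feeding multi-domain trees are named with positional
suffixes (`N`, `M`/`M1`, `M2`, ..., `C`) after their protein.

# Duplication and selection

Tandem duplicates are homology-connected gene pairs at adjacent ranks
(rank difference exactly 1) on one chromosome. Collinear blocks chain
homology anchors between two genomes by dynamic programming: chains must
be strictly monotone in both genomes, same and inverted orientations are
searched separately, rank gaps up to 25 are allowed at a penalty of
`gap/25` per skipped rank, and chains need at least 5 anchors (the
conventional minimum). The scoring is deliberately simpler than
MCScanX-style e-value-weighted scoring — +1 per anchor minus the gap
penalty — which is sufficient for rank-indexed anchors and keeps the
procedure fully reproducible.

Ortholog pairs for family genes are their anchor mates across blocks; the
partner with minimum Ks is kept ("small Ks" operationalized), guarded by a
saturation ceiling Ks ≤ 3. Ka/Ks uses the Nei–Gojobori (1986) counting
method: per-codon synonymous site fractions with mutations to stop codons
excluded and the per-position denominator renormalized (so S + N stays 3
per codon); differences averaged over all orderings of the substitution
pathway, pathways through stop codons excluded (with an all-pathways
fallback when every ordering is blocked, and a `stop_handling = "nonsyn"`
variant that counts stop mutations as nonsynonymous); Jukes–Cantor
correction `d = -(3/4) ln(1 - (4/3) p)` applied to both proportions.
NG86 is a counting method, not a maximum-likelihood codon model: on real
data its Ka/Ks values will differ from ML estimators (PAML's) slightly and
systematically, typically by underweighting transition/transversion bias.
Selection classes follow the ratio: ω < 1 purifying, ω = 1 (within `1e-9`)
neutral, ω > 1 positive, undefined when Ks = 0. Divergence time is
`T = Ks/(2r)`; the synonymous rate `r` is lineage-specific and therefore a
mandatory argument with no default.

# Expression

Relative expression uses the comparative Ct method: replicates are
averaged on the Ct scale (the standard convention; averaging fold changes
would bias the estimate), ΔCt subtracts the reference gene per sample,
ΔΔCt subtracts the control sample, and fold change is `2^-ΔΔCt`. The
amplification efficiency is assumed exactly 2 per cycle; an
efficiency-corrected variant `E^-ΔΔCt` is available via the `efficiency`
argument. No confidence intervals are attached. Benjamini–Hochberg
adjustment of p-value vectors is delegated to `stats::p.adjust` behind an
input-validating wrapper. Matrix summaries offer `log2(x+1)` and per-row
z-scoring (constant rows map to zero rather than NaN).

# What the synthetic data emulates — and what it does not

The generator produces, under one seed, every input the pipeline reads.
Each generator draws from its own RNG stream derived from (seed,
generator name), so adding a generator never perturbs the others and
every output is byte-identical on re-run.

* **Proteomes** (`simulate_proteome()`): background proteins with glycine
  at 7% (roughly proteome-typical) and other residues uniform; planted
  members whose domain envelopes follow their class architecture with a
  ≥11/20 glycine window outside the envelopes (14 G by default); decoys
  with domain hits but windows capped at 9/20, and glycine-rich decoys
  without RRM/CSD hits; optional noise rows above the E-value threshold.
  The default mix (4 IVa, 3 IVb, 2 IVc, 3 IVd members, 4 + 4 decoys, 30
  background proteins) keeps class proportions in line with reported
  family tables at a desk-scale size.
* **Genome pairs** (`simulate_genome_pair()`): 3 chromosomes × 40 genes;
  genome B copies two 8-gene segments per chromosome (the second
  inverted) with unique genes between, drops copies at a configurable gap
  rate, and plants tandem duplicates as adjacent-rank copies between the
  two segments — placed there so a planted tandem anchor can never extend
  a planted chain, keeping the truth tables exactly recoverable. CDS for
  each ortholog pair evolve under a stated ω.
* **Codon pairs** (`simulate_codon_pair()`): per-site nucleotide
  proposals (Poisson, mean `t` per site), stop-creating proposals
  rejected, synonymous changes always accepted, nonsynonymous accepted
  with probability ω. The default `t = 0.21` was calibrated once so the
  realized synonymous divergence sits near Ks ≈ 0.2, the low-divergence
  regime where counting methods are most reliable.
* **Alignments on trees** (`simulate_alignment_on_tree()`): Poisson
  substitutions to a uniformly random different residue — exactly the
  model the Poisson distance correction inverts, which is what makes NJ
  recovery a meaningful oracle.
* **Ct tables** (`simulate_ct_table()`): reference gene constant plus
  Gaussian noise; target Ct = baseline − planted log2 effect + noise
  (default sd 0.2 cycles, 3 replicates, matching routine qPCR practice).

These simulations validate the *machinery*: that every stage recovers
exactly what was planted under its own model assumptions. They do not
establish performance on real genomes, where domain boundaries are fuzzy,
glycine content is autocorrelated, synteny decays with rearrangements and
gene loss, codon usage is biased, and qPCR noise is not Gaussian on the
Ct scale. Passing tests therefore demonstrate correctness of
implementation, not field accuracy.

# Numerical choices and degenerate inputs

* E-value and glycine thresholds are strict inequalities (`< 1e-4`,
  `> 0.5`); bootstrap collapse keeps strictly greater than the threshold.
* Bisection for pI stops at |charge| < `1e-4` or an interval of `1e-9`
  pH units; the charge function is strictly decreasing in pH, so the
  root is unique.
* NJ tie-breaks and clamping are described above; distances must be
  symmetric within `1e-8` and non-negative.
* Ka/Ks errors (rather than returning NA) on internal stops, non-ACGT
  characters, frame violations, and Jukes–Cantor saturation (p ≥ 3/4);
  a shared terminal stop codon is trimmed.
* Empty inputs: an empty proteome or empty domain table yields an empty
  roster (not an error); an empty hit list yields no tandem pairs or
  blocks; `bh_adjust(numeric())` returns `numeric()`.
* Problem sizes in the tests and the acceptance script — 1,000-sequence
  oracle sweeps, 100 additive matrices up to 12 taxa, 500 codon-pair
  oracle comparisons, 200 recovery replicates of 300 codons per ω, 100
  Ct-table replicates — were chosen as the smallest sizes at which the
  stochastic checks are stable to reruns.

# Known limitations

* The profile-HMM search itself is out of scope: hit tables are inputs.
* NG86 is the only Ka/Ks estimator; no ML codon models.
* The collinearity chainer is rank-based and single-linkage per
  orientation; it does not model block merges across chromosome fusions.
* The "linked pairs" criterion is a parameterized stand-in.
* qPCR analysis assumes equal amplification efficiency across genes
  unless told otherwise, and attaches no uncertainty estimates.

# A compact worked run

```{r example, eval = FALSE}
set.seed(1)
sim <- simulate_proteome(seed = 1)
roster <- identify_family_members(sim$proteome, sim$domain_hits)
dplyr::count(roster, family_class)

g <- simulate_genome_pair(seed = 1)
ranks_b <- assign_gene_ranks(g$genes_b)
detect_tandem_arrays(g$paralog_hits_b, ranks_b)

blocks <- chain_collinear_blocks(g$ortholog_hits,
                                 assign_gene_ranks(g$genes_a), ranks_b)
pairs <- extract_ortholog_pairs(blocks, unique(g$truth$blocks$gene_a),
                                character(),
                                make_kaks_fn(c(g$cds_a, g$cds_b)))
summary(pairs$omega)
```
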