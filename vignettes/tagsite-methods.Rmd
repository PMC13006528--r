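---
title: "Scoring proteins for non-disruptive epitope-tag insertion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring proteins for non-disruptive epitope-tag insertion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagsite)
```

## The problem

Epitope tags (such as the 14-residue V5 peptide) let commercial antibodies
detect proteins for which no good antibody exists. Terminal tags often break
function when the N or C terminus is structurally or functionally important,
so the practical question is *where inside the protein body* a tag can be
inserted with the least risk. `tagsite` scores every residue of a query
protein for insertion suitability by combining four per-residue features,
each normalized to $[0,1]$ with high values meaning "safe to insert here":

1. **Sequence conservation**, as Shannon entropy of the corresponding column
   of a multiple sequence alignment (MSA) with homologs from a panel of
   vertebrate species:
   $$H(X) = -\sum_{a} p(x_a)\,\log_2 p(x_a)$$
   summed over the 20 standard amino acids. Entropy is divided by 4.32 bits,
   the maximum entropy over 20 amino acids ($\log_2 20 = 4.32$), so a fully
   conserved column scores 0 (do not touch) and a maximally variable column
   scores 1.
2. **Secondary structure**, binned from the DSSP assignment: defined
   structure (codes G, H, I helices, E strand, P polyproline) scores 0;
   coil (C) scores 1.
3. **Relative solvent accessibility**,
   $\mathrm{RSA} = \mathrm{ACC} / \mathrm{SA}_{\max}(aa)$, the DSSP
   accessible surface area normalized by that residue type's maximum.
4. **Disordered binding regions**: ANCHOR2's per-residue probability BR that
   a disordered segment participates in a binding interaction, used as
   $1 - \mathrm{BR}$ so that predicted interaction sites score low.

Two per-residue summaries are computed. The **minimum-feature score**
$E_i = \min_f v_{i,f}$ drives ranking: a single unfavorable feature vetoes a
site. The **weighted sum** $S_i = \sum_f w_f\, v_{i,f}$ (default weights:
entropy 1.5, all others 1) is reported per residue and used as a predictor
in the benchmark module, but not for ranking. $E_i$ is smoothed with a
centered sliding window of seven residues before site selection, so that a
good position flanked by bad neighborhood is demoted.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| entropy normalizer | 4.32 | bits | maximum entropy over 20 amino acids at two decimals; `log2(20)` at full precision is selectable |
| weights $w$ | entropy 1.5, others 1 | — | conservation is the single most informative signal; tunable per protein |
| window | 7 | residues | wide enough to penalize isolated good residues in bad neighborhoods, narrow enough to keep distinct candidate regions separate |
| `top_k` | 5 | sites | reporting depth; all ties with the k-th are kept |
| `SA_max` table | theoretical maxima | Å² | the normalization scale the RSA definition cites; an empirical table is selectable by name |
| DSSP codes T, S / B | 1 / 0 | — | see below |
| probe radius / points | 1.4 Å / 960 | — | standard water probe; SASA converges to <2% at 960 points on the test fixtures |

### Terminal window handling

At the three positions nearest each terminus a full 7-residue window does
not fit. The clipped centered window is used: position 1 averages residues
1–4, position 2 averages 1–5, position 3 averages 1–6 (four to six
residues), and symmetrically at the C terminus. An alternative
(`terminal_mode = "fixed4"`), in which those positions all average exactly
the four terminal residues, is provided because both conventions are
defensible for terminal smoothing; the clipped window is the default
because it degrades gracefully to the interior rule.

### DSSP codes not covered by the binning rule

The binning rule fixes G, H, I, E, P $\to$ 0 and C $\to$ 1. Three DSSP codes
are genuinely open: turn (T), bend (S) and isolated $\beta$-bridge (B). The
defaults score T and S as 1 — they are loop-like, flexible, and tolerate
insertions the way coil does — and B as 0, since a bridge residue is
hydrogen-bonded into a strand pairing that an insertion would break. Both
sets are exposed in `structure_feature_config()` so users can recalibrate
against their own validation data.

### Other numerical choices

* **Gap handling in entropy.** Gaps and non-standard codes (X, B, Z, U) are
  excluded from column frequencies — the sum runs over the 20 standard amino
  acids, so missing data does not act as a 21st symbol. A column with fewer
  than two counted residues has entropy 0.
* **Query row.** The query sequence is counted in column frequencies like
  every other alignment row; all per-residue features are indexed on query
  positions, so columns where the query is gapped never arise.
* **RSA > 1.** DSSP ACC can exceed the tabulated maxima in extended
  conformations; the ratio is clamped to 1 to keep the feature in $[0,1]$.
* **Missing residues.** Positions absent from the DSSP output score 0 in
  both structure tracks by default (conservative: never recommend an
  unobserved position); an error policy is available.
* **Homolog selection.** One homolog per species, the BLAST hit with the
  lowest E value; ties break by higher bitscore, then file order. Species
  without hits are warned about and skipped — the species panel is fixed but
  real BLAST coverage varies, and entropy over the available rows is better
  than failure.
* **Tie-breaks in ranking.** Candidates sort by windowed $E$ descending,
  ties by ascending position (stable and reproducible). Terminal positions
  are always reported alongside the ranked list so the user can compare
  N-/C-terminal tagging directly.
* **Rounding.** Reports print two decimals; the TSV keeps full precision.

## The aligner adapter

Alignment is consumed, not implemented: `build_msa()` takes an adapter
function mapping an unaligned FASTA path to an aligned FASTA path.
`prealigned_adapter()` serves a pre-computed alignment (the fully offline
route used in all tests); `external_aligner_adapter()` wraps any
MUSCLE/MAFFT-style command (default `mafft`). The query row of the returned
alignment must reduce to the query sequence exactly, or the run aborts.

## What the synthetic generator emulates

`make_fixture_protein()` writes a mutually consistent bundle — query and
homolog FASTA, pre-aligned FASTA, a toy PDB (and optionally mmCIF)
structure, a classic-format DSSP file, an IUPred2A-style disorder file and
a BLAST tabular file — for a protein with engineered regions:

* **taggable**: alignment columns carry 8 distinct residues (entropy
  $3/4.32 \approx 0.69$), coil, ACC near $0.9\,\mathrm{SA}_{\max}$, BR near 0;
* **structured / conserved / binding**: each forces the corresponding single
  feature to veto;
* **background**: conserved (with 10% low-level substitution noise),
  helical, mostly buried, intermediate BR.

File dialects imitate the real layouts (classic DSSP fixed columns,
IUPred2A long format, outfmt-6 BLAST), so the parsers are exercised against
the real-world shape. Bundles are byte-identical per seed.

What passing on fixtures does **not** show: real proteins have correlated
features (disordered regions are both coil and solvent-exposed), alignment
gaps concentrated in loops, paralog contamination in BLAST hits, and
structure-quality variation (pLDDT) that the generator does not model. The
fixtures validate the mechanics and the ranking contract, not biological
calibration; the live-network route on real UniProt/AlphaFold inputs exists
for the latter.

## The benchmark module

There is no large labeled dataset of functional internal taggings, so the
evaluation protocol treats pathogenicity of in-frame insertion variants as
a proxy task: a logistic regression on the scoring features (entropy, RSA,
secondary-structure score, DBR, $S_i$, $E_i$, plus a one-hot encoding of
the DSSP code with the reference level dropped) is fit on a stratified
80:20 split and evaluated by
$$\Pr = \frac{TP}{TP+FP}, \quad Rc = \frac{TP}{TP+FN}, \quad
F_1 = \frac{2\,\Pr\,Rc}{\Pr + Rc},$$
with pathogenic as the positive class and a 0.5 threshold. The package
ships a class-conditional simulator in place of the curated
ClinVar/VariBench data (whose acquisition is out of scope; the TSV schema
is documented for users who have it): benign variants are drawn with
feature distributions shifted toward taggable contexts, pathogenic the
reverse, with 401/433 class sizes by default, and $S_i$/$E_i$ always
computed from the sampled features through the scoring functions. Design
choices here: the split is stratified (the protocol only fixes "80:20";
stratification keeps both classes in small test sets), the threshold is
0.5, the fit is unregularized, and the number of repeated splits behind a
reported mean/s.d. is a parameter of `repeat_eval()`.

The module is validated by its statistical properties, each of which the
test suite computes: perfect class separation gives $F_1 = 1$ on held-out
data; zero separation gives chance-level $F_1$ (~0.5 for balanced classes)
across 20 repeated splits; confusion counts always partition the test set;
mean $F_1$ is monotone in class separation; and coefficient signs recover
the generative feature directions at $n = 2400$. Reproducing published
$F_1$ comparisons against external pathogenicity predictors would require
the curated dataset and those predictors, and is deliberately not attempted.

## Problem sizes

The test suite and the acceptance script use fixtures of length 40–100 with
20 fixture seeds for site recovery, simulated benchmarks of 300–834
variants with 20 repeated splits, and SASA cross-checks on 10–12-residue
toy structures — sizes at which every property being asserted is already
stable, while the whole suite runs in well under a minute.

## Known limitations

* Secondary structure and accessibility come from a single static predicted
  structure; conformational flexibility is only seen indirectly via ANCHOR2.
* The entropy feature treats the homolog panel as exchangeable evidence; no
  phylogenetic down-weighting of closely related species.
* The built-in Shrake-Rupley fallback scores a structure without DSSP as
  all-coil (secondary structure cannot be derived without hydrogen-bond
  assignment), which inflates the SS feature; it is a fallback, not a
  substitute for DSSP output.
* Tag-specific effects (tag length, charge, the 3xV5 case) are outside the
  scoring model: the score says where the backbone tolerates insertion, not
  which tag to insert.
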