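# tagsite

Scores every residue of a protein for its suitability as an epitope-tag
insertion site, so that a tag (e.g. V5) can be placed where it is least
likely to disrupt function.

Good antibodies do not exist for most of the vertebrate proteome, and
N-/C-terminal tags often kill function when the termini matter. `tagsite`
ranks *internal* insertion positions by combining four per-residue features,
each normalized to [0, 1] with high = safe:

- **conservation** — Shannon entropy of the residue's MSA column over a
  panel of vertebrate homologs, `H = -Σ_a p(x_a) log2 p(x_a)`, divided by
  4.32 bits (the maximum over 20 amino acids);
- **secondary structure** — DSSP codes binned: defined structure
  (G/H/I/E/P) → 0, coil (C) → 1;
- **relative solvent accessibility** — `RSA = ACC / SA_max(aa)`, clamped
  to 1;
- **disordered binding regions** — `1 − BR`, the complement of the ANCHOR2
  binding propensity.

Per residue *i* it computes the minimum-feature score `E_i = min_f v_if`
(one bad feature vetoes a site) and the weighted sum
`S_i = Σ_f w_f v_if` (default weights: entropy 1.5, others 1), smooths
`E` with a centered 7-residue sliding window (clipped to 4–6 residues at
the termini), and ranks positions by the windowed score, always reporting
the N- and C-terminal scores alongside for comparison.

The package also ships parsers for the interchange formats involved
(FASTA, PDB/mmCIF, classic- and mmCIF-dialect DSSP output, IUPred2A long
output, BLAST tabular), a deterministic Shrake–Rupley SASA fallback, a
synthetic fixture generator for fully offline testing, and a benchmark
harness that fits a logistic regression on the features of labeled
in-frame insertion variants (stratified 80:20 split; precision, recall,
F1).

## Worked example

Score a synthetic protein whose residues 40–50 are engineered to be
taggable (variable alignment columns, coil, exposed, no predicted binding):

```r
library(tagsite)

fx  <- make_fixture_protein(fixture_spec(length = 100, seed = 7))
cfg <- run_config(sequence  = fx$paths$query,
                  alignment = fx$paths$alignment,
                  dssp      = fx$paths$dssp,
                  anchor2   = fx$paths$anchor2)
run_pipeline(cfg)
#> Tag-insertion site report for FIXTURE_L100_S7
#>  query length: 100 residues
#>  top candidate sites (windowed minimum-feature score):
#>    position   43  windowed 0.69  raw 0.69
#>    position   44  windowed 0.69  raw 0.69
#>    position   45  windowed 0.69  raw 0.69
#>    position   46  windowed 0.69  raw 0.69
#>    position   47  windowed 0.69  raw 0.69
#>  terminals:
#>    position    1  windowed 0.00  raw 0.00
#>    position  100  windowed 0.00  raw 0.00
```

The top candidates sit inside the engineered region: their windowed
minimum-feature score of 0.69 is the entropy of an 8-way variable column
(3 bits / 4.32) — the limiting feature there — while both termini score 0
(vetoed by conservation and structure). The run also writes
`residue_scores.tsv` (one full-precision row per residue: position, aa,
the four features, `e_min`, `s_weighted`, `e_windowed`) and
`tag_sites.json` (the ranked candidates) into `cfg$out_dir`.

For real proteins, supply your own inputs: the query FASTA, either a
pre-aligned FASTA (`alignment =`) or homolog FASTA plus an aligner adapter
(`external_aligner_adapter("mafft")`), the DSSP output for the (e.g.
AlphaFold-) predicted structure, the IUPred2A/ANCHOR2 per-residue file,
and optionally a BLAST tabular file for best-hit-per-species homolog
selection over the default seven-species vertebrate panel. A thin CLI with
`score`, `benchmark`, `fixtures` and `fetch` subcommands is installed at
`inst/cli/tagsite.R`.

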