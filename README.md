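# venomtx

Analysis toolkit for venom-gland EST transcriptomes of disulfide-rich
peptide toxins, built around the fishing-spider (*Dolomedes*) venom
precursor model.

Single-pass sequencing of a venom-gland cDNA library yields a few hundred
ESTs; the analytical chain that turns them into toxin biology is:

1. **EST pipeline** — polyA trimming, >400 bp clone filtering, identity
   clustering into contigs/singletons, composition (toxin / cellular /
   unknown) and cluster-size statistics.
2. **Precursor annotation** — ORF finding and parsing of each precursor
   into signal peptide (16–25 aa), optional propeptide (12–38 aa ending in
   a Processing Quadruplet Motif: R with a preceding E), and mature toxin
   (35–86 aa), with trimming of C-terminal `G`/`GK`/`GR` amidation
   signals.
3. **Cysteine patterns** — extraction of inter-cysteine spacing
   (`-Cx6-Cx3-Cx-CCx6-…-C-` notation), canonicalization into spacer-free
   *skeletons* (`CC` adjacent / `CXC` single / `-` variable), detection of
   the Principal Structural Motif (six residues between C1–C2, none
   between C3–C4) and Extra Structural Motif (paired `CXC` in the
   C-terminal framework), and disulfide capacity `floor(n_cys/2)`.
4. **Mass & pI** — monoisotopic/average masses with disulfide and
   amidation corrections, Henderson–Hasselbalch bisection pI, and greedy
   closest matching of calculated vs observed MALDI-TOF masses.
5. **Comparative analysis** — Needleman–Wunsch identity distances,
   Saitou–Nei neighbor-joining trees with column-bootstrap support, and
   cross-species family classification (skeleton group, then ≥40%
   identity components) with a shared/specific report.
6. **Synthetic libraries** — a seeded generator emitting FASTA reads plus
   a full ground-truth table (region coordinates, amidation, skeleton,
   family), so the entire chain is testable without external data.

## Worked example

```r
library(venomtx)

# the published family-D pattern string, parsed and canonicalized
p <- parse_pattern_string(dolomedes_family_patterns()[["D"]])
p
#> <cys_pattern> 8 cysteines: Cx6-Cx6-CCx4/8-Cx1-Cx6/7-Cx1-C-
skeletonize(p)
#> <cys_skeleton> 8 cysteines: C-C-CC-CXC-CXC
detect_psm(p); detect_esm(p)
#> [1] TRUE
#> [1] TRUE

# skeleton census over both species' printed patterns
count_distinct_skeletons(c(as.list(dolomedes_family_patterns()),
                           as.list(mizhoanus_specific_skeletons())))$n_distinct
#> [1] 7

# generate a family-D-like precursor and parse it back
set.seed(7)
pre <- generate_precursor(default_family_templates()$D)
parsed <- parse_precursor(pre$aa, id = "demo")
parsed
#> <toxin_precursor> demo
#>   signal    1-25
#>   propeptide 26-58
#>   mature    59-109  (amidated, -GK)
peptide_mass(parsed$mature, "average", n_disulfides = 4, amidated = TRUE)
#> [1] 5988.11
compute_pi(parsed$mature)
#> [1] 9.06   # basic, as expected for this family
```

The pattern `C-C-CC-CXC-CXC` with PSM and ESM marks putative ion-channel
blockers; the eight family patterns collapse to five skeletons (B = D,
E = F, G = H) and the two *D. mizhoanus*-specific patterns bring the
cross-species census to seven, five shared and two specific.

## Command line

`inst/cli/venomtx` exposes the pipeline as subcommands:

```sh
venomtx generate   --families A=16,B=16 --out-prefix sim_ --seed 1
venomtx ests       --fasta reads.fa --annotations ann.tsv --min-len 400
venomtx precursors --fasta toxins.fa --pqm-acidic E
venomtx patterns   --in mature.fa --out profiles.tsv
venomtx match-ms   --mature mature.fa --observed masses.tsv --tol 1.0
venomtx tree       --fasta both_species.fa --out tree.nwk
venomtx report     --fasta both_species.fa --identity 0.4
```

See `vignettes/venom-transcriptome-methods.Rmd` for the model, parameter
defaults, generator idealizations and known limitations.
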