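---
title: "Methods: venom-gland EST analysis and toxin precursor annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: venom-gland EST analysis and toxin precursor annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomtx)
```

## Scope and model

`venomtx` analyses venom-gland EST (expressed sequence tag) libraries of
disulfide-rich spider toxins, of the kind produced by single-pass Sanger
sequencing of a directional cDNA library. The biological model is the
canonical spider-toxin precursor:

* a **signal peptide** of 16–25 hydrophobic residues,
* an optional **propeptide** of 12–38 residues whose C-terminal cleavage
  site is a Processing Quadruplet Motif (PQM),
* a **mature toxin** of 35–86 residues carrying 8–12 cysteines in a
  family-specific pattern, with an optional C-terminal amidation signal
  (`G`, `GK` or `GR`) that is trimmed during post-translational processing.

Everything downstream — pattern skeletons, PSM/ESM motifs, masses, pI,
family classification, trees — operates on the mature peptide deduced from
this parse.

## Precursor parsing rules and their parameters

**ORF finding** (`find_orf`) scans the three forward frames (the library is
directional) for the longest ATG-to-stop reading frame, ties to the
earliest start. ORFs under `min_codons = 30` are flagged and skipped: a
toxin precursor is at least signal (16) + mature (35) residues, so the
floor only removes junk.

**Signal cleavage** (`split_signal`). External predictions (e.g. SignalP)
are validated against the canonical 16–25 range and applied verbatim. The
built-in heuristic — the cut position in 16..25 with a small residue
(A/G/S/C/T) at the cut maximizing mean Kyte–Doolittle hydropathy of the
prefix, smallest position on ties — exists so that synthetic tests run
closed-loop. It is *not* a SignalP replacement; real analyses should pass
predicted sites.

**PQM cleavage** (`find_pqm_cleavage`). The motif is operationalized, as
in the spider-toxin literature, as an arginine at the cleavage position
with at least one glutamate among the three preceding residues (the acidic
set is a parameter; `c("E", "D")` is a common relaxation). Remainder
positions 12..38 are scanned and the *last* qualifying position wins.
When cleaving would leave a mature peptide under 33 residues the parser
prefers "no propeptide": the mature length bounds are hard constraints,
and three of the eight families genuinely lack a propeptide.

**Amidation** (`detect_amidation`): trailing `GK`/`GR` (two-residue
signals take precedence) or `G` are trimmed and the peptide flagged
amidated.

## Cysteine patterns, skeletons, PSM/ESM

A pattern (`extract_pattern`, `parse_pattern_string`) is the ordered list
of inter-cysteine gaps; notation `-Cx6-Cx3-Cx-CCx6-…-C-` with `xA/B`
alternative sets, bare `x` = 1, `xn` = variable, and hyphen-only gaps
variable. Unicode dashes, underscores and stray whitespace in published
strings are normalized before parsing.

The **skeleton** (`skeletonize`) collapses each gap to one of three
classes — adjacent (0, `CC`), single (1, `CXC`), variable (≥ 2 or
unspecified, `-`) — and pairs the class sequence with the cysteine count.
This canonicalization is chosen because published skeleton strings keep
`CC` and `CXC` units but collapse numbered spacers; requiring equal
cysteine counts prevents, say, a 12-cysteine and a 10-cysteine framework
with the same class prefix from merging. Under it the eight family
patterns collapse to five skeletons (B = D, E = F, G = H), and the two
*D. mizhoanus*-specific strings bring the census to seven.

**PSM** is exactly six residues between cysteines 1–2 and none between
3–4. **ESM** is a pair of `CXC` units in the C-terminal region of the
framework; since "C-terminal region" is not quantified in the source
literature we fix it, configurably, at the trailing half of the cysteine
framework (`region_fraction = 0.5`): gaps whose left cysteine index
exceeds `n_cys/2`.

A gap set that mixes skeleton classes (e.g. `{1, 4}`) is an error rather
than silently resolved: such a pattern is ambiguous between frameworks.

## Masses, pI, mass matching

Peptide masses are residue-table sums plus water; each disulfide removes
2 H (2.0157 Da mono) and C-terminal amidation replaces OH with NH2
(−0.984 Da mono). **Average** mass is the default for matching MALDI-TOF
linear-mode masses of 3–9 kDa toxins; monoisotopic is available. The
default matching assumption is the fully oxidized peptide (all cysteines
paired) with amidation as detected.

The pI (`compute_pi`) is found by bisection on the Henderson–Hasselbalch
net charge to |Z| < 1e-4 on pH 0–14. The default pKa set is the
Bjellqvist-style peptide-calibrated table used by common proteomics tools;
a free-amino-acid ("lehninger") set is included — the two differ by up to
~0.5 pH units on small peptides (glycine: 5.52 vs 5.97). Note that the
|Z| tolerance, not a pH tolerance, terminates the search: on very flat
charge curves the returned pH can sit a few hundredths from the exact
root, which is far below the precision at which pI is interpreted.

Mass matching (`match_masses`) is greedy one-to-one closest matching with
a ±1.0 Da default tolerance (MALDI-TOF linear-mode scale; the source
analysis states none, so it is a flag). Ties break by peptide id so the
output is order-invariant. Unmatched entries are reported, not dropped:
peptides below detection or carrying unmodelled PTMs are expected misses.

## EST pipeline

PolyA tails are maximal terminal `A` runs of at least `min_tail = 6`
(generated tails are 8–30 nt, so always removable). The clone-length
filter is strict (`length > 400`), matching the selection rule of the
emulated protocol; a ≤ 5% `N` screen stands in for chromatogram quality.
Clustering is single linkage: reads join when their best ungapped overlap
— candidate diagonals from shared 21-mers, both orientations — reaches
95% identity over ≥ 100 nt. `N` never counts as a match. This replaces a
proprietary assembler; cluster *memberships*, not consensus base calls,
are the analysis object, and the published 83-cluster figure depends on
unstated assembler parameters we do not attempt to reproduce.

Composition percentages use largest-remainder rounding so they sum to
100; this reproduces the published 71/24/5 split of 190/65/12 (plain
rounding would print 4% for 12/267 = 4.49%).

## Comparative analysis

Distances are `1 − identity` from end-to-end Needleman–Wunsch alignment
(match 1, mismatch −1, gap −2, deterministic traceback), computed on
mature peptides — family descriptions compare matures, and signal peptides
are conserved enough to blur family boundaries. The NJ implementation
follows Saitou–Nei with the standard limb-length formulas; ties in the
Q-criterion break lexicographically by cluster representative labels, and
negative branch lengths are clamped to zero with a warning. Bootstrap
support resamples alignment columns with replacement under a fixed seed
and reports, per original split, the fraction of replicate NJ trees
containing it. The multiple alignment is consumed as a character matrix;
the package does not re-implement an MSA tool.

Family classification partitions peptides by skeleton first, then by
connected components of the ≥ 40% identity graph within each skeleton.
The 40% default sits below the 70–90% within-family identities and above
the ~31% cross-family floor reported for these toxins. Families are
labelled by decreasing size; a family is *shared* when both species
contribute members.

## The synthetic library: what it emulates, what it does not

`generate_library` emits a directional EST library with full ground
truth: per-family toxin transcripts (reverse-translated with random
codons, A-free UTRs, 8–30 nt polyA), cellular/unknown decoy reads, copy
numbers drawn from the published cluster-size prevalence (58:19:4:2 over
bins 1, 2–9, 10–19, 20–70), per-copy substitution noise (default 0.01 —
single-pass read scale), and a master seed with per-record counter-derived
streams so records are order-independent and output is byte-identical
across runs. The default category mix is 190/65/12, the composition of
the 267-EST library it emulates.

Three generator choices are deliberate idealizations:

* **Guard zones.** The parser's two scan heuristics would otherwise face
  genuinely ambiguous inputs. The generator keeps small residues
  (A/G/S/C/T) out of precursor positions 16–25 except at the true signal
  cut, draws the signal of propeptide-less precursors long enough that
  the first cysteine clears position 25, and keeps arginine out of
  remainder positions ≤ 38 beyond the true PQM. Noise-free round-trips
  are therefore exact by construction — a green round-trip test
  establishes that the parser implements its stated rules, *not* that
  those rules resolve ambiguity in real sequences.
* **Founder homology.** Family members diverge from a family founder at
  0.1/position (cross-species founders at 0.15), mirroring real
  within-family identities of 70–90%. Independent random draws would sit
  near 25–35% identity and no identity threshold could group them.
* **UTR content.** UTRs are drawn A-free so no decoy ATG or spurious ORF
  can outrun the real one, and long enough (3' UTR 200–400 nt) that every
  toxin cDNA passes the > 400 bp clone filter. Real UTRs contain A,
  chimeras and vector sequence; none of that is modelled.

The generator does not simulate chromatogram quality, indels, chimeras or
vector contamination, and decoy reads are random sequence — their content
is irrelevant because category labels come from the annotation table, as
in the emulated analysis (where they come from BLAST).

## Numerical and degeneracy conventions

Coordinates are 1-based inclusive. Cluster and family output orders are
deterministic (size-descending, then lexicographic by radix order, so
locale-independent). Peptides with fewer than two cysteines are flagged
`acyclic` and excluded from scaffold grouping but profiled otherwise.
An equal-distance matrix yields a deterministic NJ topology via the
tie-break. `trim_polya` on an all-A read returns an empty, flagged read.

## Known limitations

* The signal-cut heuristic is a stand-in; feed external predictions for
  real data.
* Only the PQM cleavage signal is modelled; the other propeptide
  processing signals alluded to in the source literature must be given as
  explicit sites.
* Identity clustering does not produce consensus sequences, and the exact
  published contig/singleton split is out of reach by design.
* Disulfide *capacity* (`floor(n_cys/2)`) is reported, not connectivity;
  no structural claims (ICK or otherwise) are computed.
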