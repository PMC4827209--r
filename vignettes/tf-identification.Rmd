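---
title: "Rule-based transcription-factor identification and comparison in algae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based transcription-factor identification and comparison in algae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycotf)
```

## The problem and the model

Transcription factors (TFs) bind specific promoter motifs through a
DNA-binding domain (DBD), and TF families are defined by which DBD (or
combination and copy number of DBDs) a protein carries. Identifying the TF
complement of a predicted proteome therefore reduces to three steps:
collect homology evidence, remove false positives per evidence channel,
and map each protein's surviving DBD content onto a family through
explicit assignment rules.

`phycotf` implements that model as a library plus a thin command-line
wrapper. Three evidence channels are supported, each consumed as files
produced by the standard scanners (running the scanners is out of scope):

* **BLAST** similarity search against a reference TF database, in the
  12-column tabular format. The reference database is expected to encode
  each subject's family label as the id prefix before the first `|`
  (e.g. `bZIP|ref1`), which is what allows family inheritance for
  candidates with similarity evidence only.
* **Profile HMMs** via the per-domain table (`domtblout`) of `hmmscan`,
  used for custom DBD profiles not covered by the member-database
  consortium (G2-like, NF-YB, NF-YC, VARL and the like, bundled as
  `CUST_*` accessions). The per-domain *independent* e-value, not the
  full-sequence e-value, becomes the hit's e-value, because filtering and
  copy-number rules operate on individual domain instances.
* **InterProScan** TSV annotation from the member-database consortium,
  one row per signature match.

All alignment coordinates are 1-based inclusive in both input dialects and
throughout the package; no other module converts coordinates. Duplicate
FASTA ids are a hard error rather than silently suffixed, because every
downstream join keys on the protein id.

## Filtering thresholds

`filter_thresholds()` carries the operating point, configurable per run:

| parameter            | default | unit     | role |
|----------------------|---------|----------|------|
| `blast_max_evalue`   | 1e-10   | e-value  | similarity-search significance |
| `blast_min_identity` | 35      | percent  | rejects remote/spurious alignments |
| `blast_min_alnlen`   | 100     | residues | rejects short local matches |
| `ipr_max_evalue`     | 1e-3    | e-value  | member-database annotation cut |
| `hmmer_policy`       | per-profile | —    | curated score cutoff per profile |
| `hmmer_fixed_evalue` | 1e-5    | e-value  | fallback for profiles without a cutoff |

Three conventions deserve a note:

* **All comparisons are inclusive** (≥ 35, ≥ 100, ≤ 1e-10, ≤ 1e-3). The
  thresholds are quoted without strictness in the sources they come from;
  inclusive is the conventional reading, and the boundary cases are
  tested explicitly.
* **The annotation e-value cut is "at most 1e-3"**. The phrase "e-value
  above or equal to 10^-3" that sometimes accompanies this threshold in
  pipeline descriptions would, read literally, *keep* the noise and
  discard the good matches; since the step exists to remove false
  positives, it is implemented as `evalue <= 1e-3`. The threshold is
  configurable for users who disagree.
* **Best-hit ties are broken deterministically** (bit score, then
  e-value, then lexicographic subject id), so identical inputs always
  produce byte-identical outputs.

Per-profile score cutoffs play the role of curated gathering thresholds.
The custom profiles ship with conservative cutoffs (20-22 bits) in
`inst/extdata/hmm_profile_thresholds.tsv`; profiles without a cutoff fall
back to the fixed e-value test.

## The rules engine

A rule file (`inst/extdata/family_rules.tsv`) is a flat table: one record
per family or subfamily with required accession sets (the protein must hit
at least one accession from *every* set), per-set minimum copy numbers,
forbidden accessions, and a unique integer priority. A protein is assigned
the highest-priority matching rule; priorities encode
"most-specific-first" — multi-domain and copy-number rules (GARP-ARR-B,
C2C2-CO-like, AP2, DBB, the NF-Y subunits) outrank broad single-domain
rules (ERF, C2H2, HB-other, MYB-rel). Explicit integers were chosen over
implicit specificity scoring because they make conflict resolution
auditable and editable in the data file rather than in code.

Copy numbers count *non-overlapping* domain instances: instances are
selected greedily in ascending alignment-start order, and an instance
overlapping an already selected one by more than 50 % of the shorter
alignment is not counted. The greedy selection is compared against a
brute-force maximum-compatible-subset oracle in the test suite.

Proteins matching no rule are labelled `unclassified` and retained in the
output (excluded from TF counts), so pipeline debugging does not lose
records. Proteins whose only surviving evidence is a best BLAST hit
inherit the family of the matched subject; a strict mode (`require_dbd =
TRUE`, CLI flag `--require-dbd`) disables that path.

The bundled rule content — which Pfam-style accession stands for which
family — is a curated reconstruction and explicitly *data, not
algorithm*: family definitions compiled from the public plant/cyanobacterial
TF databases differ in detail, and the file is meant to be replaced or
versioned by the user. The classification machinery is indifferent to the
specific accession strings.

## Curation heuristics

Four special cases are automated:

* **MYB relaxed path.** E-value validation of MYB-domain annotations
  produces false negatives (MYB repeats are short and often score weakly),
  so MYB accessions bypass the InterProScan e-value cut. Hits kept only
  through the bypass are marked, and assignments relying on them carry the
  `myb_relaxed_path` flag.
* **MYB repeat classes.** The number of non-overlapping MYB repeats
  decides the class: ≥ 3 → `MYB (3R)`, 2 → `MYB (2R)`, 1 → `MYB-rel`.
* **SHAQKYF.** The SHAQKYF subclass of MYB-related TFs is named for a
  signature in its recognition helix but has no published motif
  definition; the package uses the amino-acid pattern `S-H-[AL]-Q-K-[YF]`
  scanned inside each MYB repeat's aligned subsequence, configurable as a
  regex in the rules file. A match reclassifies `MYB-rel` to
  `MYB-SHAQKYF` (flag `shaqkyf_motif`).
* **G2-like cross-annotation.** The G2-like DBD is closely similar to the
  MYB-SHAQKYF domain and absent from the member-database consortium. Any
  protein carrying both a G2-like profile hit and a SHAQKYF call is
  re-scored: the higher profile bit score wins (flag
  `g2like_crosscheck`). When one side has no bit score (annotation-only
  evidence), the scored profile wins.

## Accuracy benchmarking

Per family, with predictions and gold standard sharing an id space:
sensitivity = TP/(TP+FN), PPV = TP/(TP+FP). Undefined ratios (empty
denominator) are reported as `NA`, never 0 or 1, to avoid inflating
summaries. Two display conventions coexist deliberately:

* **Accuracy ratios are displayed truncated to two decimals**: a PPV of
  224/225 prints as 0.99, not 1.00, because a value below one is exactly
  the flag that false positives were included — rounding it up to 1 would
  erase the information the number exists to convey.
* **Proportions (percentage tables) are displayed half-up**, the ordinary
  convention for percentage tables.

Raw ratios are always retained in the machine-readable columns.

## The comparative layer

`count_table()` aggregates per-species assignments into a species ×
family matrix (unclassified records excluded); `proportions()` converts to
percentages of each species' TF complement. The package bundles a
published seven-algae count table (`algal_tf_counts()`, 7 species × 41
family rows) as the worked substrate. One wrinkle is carried explicitly:
in the published table the *Porphyridium purpureum* column's per-family
counts sum to 198, while every printed percentage in that column
back-computes against the published total of 199 (a single-cell count typo
in the original). `tf_count_table()` therefore accepts an explicit
`totals` override, and the bundled loader uses the published totals so the
printed percentages reproduce exactly.

* **Presence/absence and dendrogram.** `presence_absence()` is the
  indicator of count > 0 at the family-row level of the table. At that
  level the chlorophyte column has 38 nonzero rows; collapsing the two
  AP2/ERF subfamily rows into their superfamily gives the 37 families
  usually quoted for it — both readings are tested, neither is hidden.
  `tf_dendrogram()` clusters species rows with Euclidean distance and
  complete linkage by default. The source analysis named neither metric
  nor linkage, only that a similarity matrix was clustered in R; the R
  defaults (`dist`'s Euclidean, `hclust`'s complete) are the natural
  reconstruction, and both are configurable. The lineage topology
  (haptophyte clade with the two coccolithophore-line species as sisters;
  chlorophyte deepest) is asserted at topology level only — branch
  lengths are not comparable across metric choices.
* **Family clustering.** `family_clusters()` clusters family rows of the
  proportion table (same defaults, raw proportions, `k = 4` matching the
  four described cluster classes; row scaling by flag). With the bundled
  table the nine green-lineage families (SBP, VARL, Whirly, WRKY,
  S1Fa-like, NF-X1, C2C2-CO-like, C2C2-Dof, GARP-ARR-B) fall in one
  cluster.
* **SHAQKYF ratio.** `shaqkyf_ratio()` uses the union denominator
  100·SHAQKYF/(SHAQKYF + MYB-rel). This is the only convention consistent
  with the three published stramenopile/rhodophyte percentages (50, 53.3,
  69.6); the published values for *Pavlova* sp. and *Chlamydomonas
  reinhardtii* (13.3, 22.2) instead follow SHAQKYF/MYB-rel alone, and the
  *Tisochrysis lutea* value (4.7) matches neither convention exactly
  (1/22 = 4.5, 1/21 = 4.8). The union convention is implemented; the
  discrepancy is documented here rather than resolved.

## The synthetic fixture generator

`generate_proteome()` plants, for each requested family, proteins whose
architecture follows the family's rule: uniform random amino-acid
background with fixed recognizable placeholder peptides at the planted
coordinates (50-residue domains, 20-residue gaps). Placeholders are
deterministic per accession and exclude histidine, so the SHAQKYF pattern
can only occur where it is planted inside a MYB repeat.
`generate_evidence()` writes real files in all three dialects — Pfam-style
accessions to the InterProScan channel, `CUST_*` accessions to the
domtblout channel, and a passing best BLAST hit per planted protein plus
sub-threshold decoy rows that the filter engine must remove even at zero
noise.

The noise model is deliberately simple and fully bookkept:

* `fn_rate` drops individual planted domain instances. The RNG order is a
  documented contract (first one uniform draw per architecture row, then
  the false-positive draws), so tests recompute the planted drops
  independently from the seed.
* `fp_rate` injects spurious significant hits on *background* (non-TF)
  proteins, drawn from single-copy families only, so each spurious hit
  maps to one predictable family label and PPV degrades while sensitivity
  stays exact.

Noise studies are run in strict mode (`require_dbd = TRUE`) and without
the BLAST channel, so that a dropped domain translates into a
classification loss rather than being rescued by similarity inheritance;
at the default settings the rescue path is itself exercised by the
zero-noise tests.

What the generator emulates is the *logical* content of the evidence
files, not biology: no sequence evolution, no alignment uncertainty, no
correlated errors between channels, no e-value distributions (constants
on either side of the thresholds). Passing the closure tests therefore
shows that the plumbing, filtering and rule logic are correct — it says
nothing about scanner sensitivity on real proteomes.

## Problem sizes and numerical choices

The test suite and the acceptance script use a 60-protein closure fixture
(5 proteins × 12 families covering every classification mechanism, plus
background proteins), 30-protein noise fixtures, and the bundled 7 × 41
count table; the full suite runs in well under a minute on one CPU. These
sizes were chosen as the smallest that exercise every code path —
copy-number rules need ≥ 2 planted copies, the motif path needs planted
and motif-free repeats, clustering needs all 41 family rows.

Degenerate inputs are defined, not accidental: empty evidence files parse
to empty record sets; a proteome with no evidenced protein classifies to
an empty assignment table; ratios with empty denominators are `NA`;
dendrograms require ≥ 2 species; zero-total species are an error naming
the species.

## Known limitations

* The bundled accession-to-family mapping is representative, not
  exhaustive; real annotation work should review and extend the rules
  file (multiple accessions per set are supported).
* Per-residue overlap resolution between member databases is not
  attempted; copy counting uses the 50 %-of-shorter-alignment rule only.
* BLAST-only inheritance trusts the reference database's label encoding;
  with a mislabelled reference, strict mode is the safe setting.
* The comparative layer reproduces published full-proteome results only
  at the level of their printed count tables; re-deriving them would
  require the external proteomes and reference databases, which is out of
  scope by design.
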