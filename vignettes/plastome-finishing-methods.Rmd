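---
title: "Methods: plastome finishing, structural variants, and HGT verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome finishing, structural variants, and HGT verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

## Scope and model

`plastomics` treats a plastome as a circular DNA molecule with the
canonical quadripartite arrangement LSC → IRb → SSC → IRa, where IRa is
the exact (or near-exact) reverse complement of IRb. All coordinates in
the package are 1-based closed intervals, the convention of the R and
Bioconductor ecosystem (IRanges, GFF3) this package interoperates with;
the circle's origin is the first base of the LSC in canonical
orientation. Circularity is handled by explicit wrap-around arithmetic;
sequence doubling is used only inside search routines, never in stored
objects.

The package covers the desk-scale part of a short-read plastome
project: simulating study-shaped data with known truth, finishing a
fragmented assembly against a reference, canonicalizing and annotating
the finished circle, calling the large structural events that serve as
clade markers, verifying a putative mitochondrion-to-plastid transfer,
and building character matrices for downstream phylogenetics. Read
quality control, de Bruijn assembly itself, multiple alignment of real
130 kb matrices, substitution-model selection and tree inference are
deliberately out of scope; established external tools own those steps.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every downstream stage is validated.

* **Genome shape.** Defaults are bamboo-sized: LSC 82 kb, SSC 12.8 kb,
  IR 21.8 kb (total ~138 kb), and the validation batteries draw region
  lengths uniformly from the published ranges (LSC 79.5–83.3 kb, SSC
  12.4–13.7 kb, IR 19.8–25.0 kb, totals 135–144 kb). Background
  composition is 61% AT, the plastome-typical value; foreign
  (mitochondrial-like) insert payloads default to 55% AT. At these
  lengths the binomial concentration of the AT fraction makes the
  insert/background contrast detectable for inserts of ~2 kb and up.
* **Genes.** A packaged list of canonical grass plastid genes in
  conserved genome order populates the LSC, IR and SSC, so intergenic
  spacer names such as `rps16-trnQ`, `trnD-psbM` and `rpl23-ndhB` are
  meaningful loci. Gene lengths are drawn from plausible ranges (tRNAs
  72–90 bp, rRNAs at their known sizes, CDS 300–1500 bp) and compacted
  proportionally when a miniature test genome is requested. The
  orientation marker psbA is always placed on the forward strand; it is
  how `canonicalize()` resolves the strand of a finished genome.
* **Boundary guards.** Two constructions make truth comparisons exact
  rather than approximate. The bases immediately outside the IR pair
  are resampled so they do not extend the reverse-complement symmetry:
  otherwise the maximal IR would, with probability ~1/4 per junction,
  be one base longer than the annotated one. Likewise inversion sites
  are slid by up to ±5 bp to a position where the first base of the
  interval is not the complement of the last, otherwise the planted
  interval is not the unique maximal representation of the event.
* **Variants.** Insertions are planted mid-spacer; a payload landing in
  the IR is mirrored (reverse-complemented) into the other copy, since
  a real IR-resident insert exists in both repeats — so planting a
  2,706 bp insert in `rpl23-ndhB` lengthens the genome by 5,412 bp and
  yields two truth records flagged `mirrored`. Mirroring can be
  disabled per call. An inversion with a `flank_repeat` motif gets a
  concrete instance of the motif planted immediately 5' and its reverse
  complement immediately 3'; because the flanks pre-date the inversion
  biologically, `plant_variants()` also returns the `ancestral` genome
  (flanks planted, variants absent) as the correct comparison point.
* **Reads.** Uniform starts on the circle, both strands, 99–100 bp,
  i.i.d. substitution errors up to 5%, constant high quality (quality
  trimming is out of scope). Paired mode draws normal fragment lengths
  (default 300 ± 30 bp) and reports convergent mates. Read count is
  `round(coverage * L / read_len)`, so the realized mean mapped depth
  is within a few percent of the request.

Everything is reproducible bit-for-bit from `(spec, seed)`; seeds are
applied with `withr::with_seed`, so the caller's RNG state is never
disturbed.

What the generator does *not* emulate: indel sequencing errors,
quality-score decay, GC-dependent coverage bias (beyond the one AT
knob), chimeric fragments, or library-preparation composition bias —
the observed under-representation of GC-rich fragments after PCR has no
quantitative model to copy. Tests passing on synthetic data therefore
demonstrate algorithmic correctness under clean conditions, not
robustness to every artifact of real libraries.

## Finishing

`scaffold_contigs()` places each contig by its longest collinear chain
of unique shared anchor k-mers (default k = 31) with the reference,
taking the strand of the winning chain. An inverted-repeat contig is
inherently ambiguous between the two copies; the forward strand wins
ties, which resolves the ambiguity deterministically and consistently
for the two IR contigs.

`close_gaps()` implements reference-guided junction joining under three
rules taken from manual finishing practice: an evidence sequence may
extend a flank only if it overlaps it by at least `min_overlap` (20 bp)
with **zero mismatches**, the overlap is anchored at a terminus of the
evidence, and a paired read additionally requires its mate within three
standard deviations of the expected insert size in convergent
orientation (the 3-sd window is this package's choice; only position
and orientation checking is prescribed by practice). Junctions are
closed preferentially by a *bridge*: a single evidence sequence whose
5' end overlaps the left flank by ≥ `min_overlap` and whose remaining
suffix (also ≥ `min_overlap`) matches the start of the reference-ordered
right-hand piece. Bridging matters at the single-copy/IR junctions,
where read evidence alone supports both structural isomers of the SSC
(the well-known flip-flop ambiguity); the scaffold order inherited from
the reference arbitrates. When no bridge exists the flank grows one
consensus base at a time: the longest-overlap admissible evidence
supplies the base and must agree with the strict majority of the other
admissible evidence — a single erroneous read can therefore never
inject a base, while a tie with no majority flags the junction as
ambiguous and leaves it open, with the partial pieces and a per-junction
status report returned. On circular closure the duplicated junction
overlap is collapsed exactly once.

`assess_assembly()` maps each read to its best location on the doubled
circle — exact hash join first, then a seeded rescue allowing ≤ 2
substitutions — computes per-position depth, and lists every position
where a strict majority of covering reads disagrees with the assembly.
Unmapped reads are ignored; in real data they may be nuclear or
mitochondrial. A read matching both IR copies is assigned the
lower-coordinate copy, which leaves the genome-wide mean depth unbiased
but concentrates IR coverage in IRb; junction-coverage ratios in the IR
can therefore exceed 1.

## Quadripartite structure

`detect_inverted_repeats()` seeds with exact 25-mer matches between the
sequence and its reverse complement, groups them along anti-diagonals,
and merges collinear runs within a mismatch budget of 0.1% of the
genome length — enough for near-identical IR copies, far too little to
bridge unrelated repeats. The search is repeated on a half-genome
rotation so a copy spanning the origin is still seen intact, making
detection rotation-invariant; a self-reverse-complementary run (a
constructed palindrome) is split into its two adjacent halves. Genomes
with no repeat ≥ `min_ir_len` return a no-IR result rather than an
error, since some plastomes genuinely lack IRs.

`canonicalize()` rotates (and if needed reflects) the circle into
LSC → IRb → SSC → IRa, labelling as IRb the copy adjacent to the 3' end
of the LSC. Between the two strand candidates it prefers the one
placing the marker gene (psbA) on the forward strand; without
annotations it takes the lexicographically smaller sequence. Both rules
are deterministic functions of the circular sequence, so
canonicalization is idempotent and invariant under every rotation and
reflection of its input.

`transfer_annotations()` seeds candidate placements with exact 25-mer
probes from each feature (three offsets, both strands — IR features
thereby reach both copies), then computes a local alignment of the
feature against each candidate window. "Similarity" is defined as
percent identity over the aligned span — the threshold's unit is not
otherwise fixed — with an added requirement that the span cover ≥ 90%
of the feature length, which suppresses spurious short high-identity
hits. The default threshold is 0.70.

## Structural variants

`anchor_align()` chains unique shared 21-mers by longest increasing
subsequence, merges same-diagonal anchors (absorbing isolated
substitutions across gaps up to 3k), extends block edges base-by-base,
and trims the overlap that breakpoint homology can create between
adjacent blocks — after which gap sizes are exact for clean planted
events. Dense anchor sets are thinned to 20,000 before chaining; edges
are recovered exactly by the extension step regardless.

`detect_indels()` emits every inter-block gap of ≥ `min_len` (100 bp) on
exactly one genome; `detect_inversions()` takes gaps present on both
genomes at comparable size and tests whether the two gap sequences
align on the opposite strand (shared k-mer vote ≥ 50%). The inverted
interval excludes the flanking repeats, because forward-strand
extension consumes the flanks, which are identical in both genomes.
The defaults (100 bp indel, 50 bp inversion) pass all four marker-sized
events (150–4,938 bp) with slack; both are exposed as arguments. A
planted-event endpoint can be ambiguous by a base or two when the
payload shares its boundary base with the reference — the classic indel
placement ambiguity — so truth comparisons use a ±2 bp endpoint
tolerance while lengths are compared exactly.

`find_inverted_flanks()` scans f from `max_flank` down and returns the
longest f for which the f bases 5' of the inversion are the
IUPAC-compatible reverse complement of the f bases 3' of it. Two codes
are compatible iff their base sets intersect (Y matches C or T, not A);
degeneracy is allowed but no incompatible position is, since the
"imperfect" repeat notion has no defined mismatch tolerance to
implement. The scan is circular, and f = 0 is a result, not an error.

`map_synapomorphies()` is deliberately thin: the tree is an input
(newick; never inferred here), monophyly of a record's taxa is tested
with ape, a monophyletic set is assigned the branch subtending its MRCA
("synapomorphy"; a single taxon is an "autapomorphy"), anything else is
"homoplastic/conflicting" with the minimal covering clade reported.

## HGT verification

Verification of a putative foreign insert combines four independent
signals, each a separate function usable alone:

* origin classification by best local alignment against user-supplied
  plastid and mitochondrial panels (no live database queries; the
  validation battery builds synthetic panels carrying a 99%-identity
  copy of the insert); calls below 70% identity or 100 bp span are
  "unclassified";
* junction depth in a 100 bp window centred on each insert boundary,
  relative to the genome mean (the mean, not the median, is used for
  "overall coverage"); a ratio < 0.25 flags a suspect boundary — the
  threshold is a policy default calibrated to separate clonally present
  inserts (ratios near 1) from reference-only sequence (ratios near 0);
* exact AT-composition contrast of insert versus remainder;
* in-silico PCR on the circular template: IUPAC-compatible annealing
  with ≤ `max_mismatch` incompatible bases, the last three 3' bases
  required incompatibility-free (a choice emulating polymerase
  3'-mismatch intolerance; the wet protocol being emulated reports only
  product sizes), every convergent site pair within `max_product`
  reported, product length measured 5' end to 5' end inclusive.

## Character matrices

`assemble_matrix()` consumes pre-aligned rows (an external aligner for
real data; `chain_to_alignment()` for synthetic pairs) with IRa removed
upstream so the repeat is not represented twice. Masks mark gapped,
inversion and coding columns. `strip_gapped_columns()` removes every
column with any gap (idempotent; column conservation holds exactly),
`mask_inversions()` removes columns overlapped by inversion records
(their cross-taxon homology is spurious), and `extract_coding()`
concatenates CDS columns in genome order normalized to the coding
strand of the reference row — reading frame across length-variant taxa
follows the reference row. Because real-data matrix dimensions depend
on the external aligner and its version, no published alignment length
is treated as a reproducible quantity here.

## Pipeline, determinism, and problem sizes

`run_pipeline()` executes simulate → finish → canonicalize → annotate →
variants → hgt → matrix under a flat key=value configuration, writing
FASTA/FASTQ/GFF3/TSV artifacts, a JSON summary with the config hash and
seed, and per-stage timings to stderr. Identical config and seed give
byte-identical summaries. A failing stage halts the run with the stage
named; artifacts already written are retained.

Problem sizes used by the test suite and the acceptance script were
chosen to exercise the full study conditions where it matters and
miniatures elsewhere: unit tests run on ~24 kb genomes with the same
quadripartite proportions; the validation batteries run 50
plant-and-recover replicates, 20 finishing round trips at 25× coverage
and 20 junction-coverage control pairs at full bamboo scale (135–144 kb
genomes drawn from the published ranges; the junction controls use
~52 kb genomes, which leave the per-window depth statistics unchanged).

## Known limitations

* Gap closure is reference-guided; with no reference-ordered scaffold
  the SSC orientation isomers cannot be told apart, as is true of any
  short-read evidence.
* The consensus extension walks one base per step; junctions separated
  by gaps much longer than a read are closed only if a spanning contig
  is supplied as evidence.
* `anchor_align()` assumes mostly-collinear genomes (true of
  plastomes); it is not a general-purpose aligner and does not model
  translocations.
* Substitution errors only; indel sequencing errors would defeat the
  zero-mismatch overlap rule more often than the error model here
  predicts.
* The annotation transfer scores identity over the best local
  alignment; features diverged beyond seed recovery (no exact 25-mer
  in any of three positions on either strand) are reported
  untransferred rather than searched exhaustively.
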