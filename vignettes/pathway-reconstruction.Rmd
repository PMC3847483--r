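---
title: "Multi-template pathway reconstruction: model, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-template pathway reconstruction: model, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the approach

When a genome of interest (the *query* species — the motivating case is a
starchy root crop whose genome was sequenced recently and is still sparsely
annotated) lacks curated pathway annotation, a species-specific metabolic
pathway can be reconstructed *inversely*: instead of annotating the query
genome and then looking for pathway genes, the pathway genes of several
well-annotated *template* species are used as probes to find their
orthologs in the query proteome. orthopath implements this framework end to
end for a reference pathway expressed as EC-numbered reactions grouped into
sub-pathways (in the motivating case: Calvin cycle, sucrose synthesis and
storage starch synthesis, from CO~2~ fixation through to storage starch).

The procedure per template gene is a two-pass reciprocal search:

1. **First pass.** The template gene is locally aligned against every query
   protein. Hits are kept only when all three critical values hold
   (inclusively): E-value ≤ 1e-10, percent identity ≥ 60 and query
   coverage ≥ 80. Identity is measured over the aligned region; coverage
   relative to the query sequence's length.
2. **Second pass.** Each surviving query protein is aligned back against
   the template species' full proteome. If the best filtered second-pass
   hit of the *best* first-pass hit is the template gene itself, the pair
   is a reciprocal best hit (RBH) — the strongest orthology evidence.
   Non-RBH survivors are annotated only if their best second-pass hit
   carries an *identical* function label (exact match after case-folding
   and whitespace normalisation).

Each (query protein, function) pair accumulates at most one evidence item
per template species, weighted by match quality `H` (1 for RBH, 0.5 for
second-pass-confirmed) and function clarity `F` (1 for clearly annotated
template genes, 0.5 for "putative"-style annotations).

## Confidence scores and regions

With `N_m` the number of template species that identified a function and
`N_t` the number of templates employed (default 5), the two confidence
scores of an annotation are

$$MS = \frac{\sum_i H_i F_i}{N_m}, \qquad CS = \frac{\sum_i H_i F_i}{N_t}.$$

The *match score* MS measures how well the annotation is supported by the
alignments that produced it; the *conservation score* CS additionally
discounts functions seen in few templates, so `CS = MS · N_m / N_t` always
holds and `CS ≤ MS`. Both scores reach 1 only for an all-template,
all-RBH, all-clear profile; an annotated protein can never score 0 (each
evidence term is at least 0.25), so 0 is the unannotated limit and
unannotated proteins are reported separately rather than as score-0 rows.

The MS–CS plane is partitioned into three confidence regions: **A** (low;
poorly matched), **B** (high; well matched but poorly conserved across
templates — a signature of lineage-specific pathway components) and **C**
(extremely high; well matched and widely conserved). The source analysis
draws these regions qualitatively; this package must pick numbers, and
defaults to `MS ≥ 0.7` for "well matched" and `CS ≥ 0.5` for "highly
conserved" (with `N_t = 5`, `CS ≥ 0.5` needs strong evidence from at least
three species). Both thresholds are arguments of `score_config()` and the
partition is total over attainable score pairs.

## The alignment engine

The original analysis delegated alignment to BLASTP; a reusable toolkit
cannot, so orthopath ships a deterministic Smith–Waterman engine
(`local_align()`, `best_hits()`) built on `Biostrings::pairwiseAlignment`:

* **Scoring.** BLOSUM62 with affine gaps, open 11 / extend 1 (a gap of
  length L costs `open + L·extend`, the BLAST convention); nucleotide mode
  uses match +5 / mismatch −4, open 5 / extend 2. Ambiguity residues (`X`
  in protein, `N` in nucleotide) score 0 against everything and never
  count as identities.
* **E-values.** The classical Karlin–Altschul formula
  `E = K·m·n·exp(−λS)` with the published gapped-BLOSUM62 constants
  λ = 0.267, K = 0.041 (protein) and the classic ungapped +5/−4 constants
  λ = 0.192, K = 0.176 (nucleotide). No composition-based or edge-length
  corrections are applied: E-values are reproducible and monotone in score
  and database size, but are *not* promised to equal BLAST's. All
  thresholds in the framework sit orders of magnitude away from the
  regimes where the correction terms matter.
* **Determinism.** A zero-score optimum is reported as "no hit" rather
  than a degenerate alignment. Among equal-scoring hits the ordering is
  bit score (desc), E-value (asc), subject id (asc); traceback ties inside
  one alignment are resolved by the alignment library's deterministic
  policy (the raw score, which all downstream decisions use, is
  tie-independent).
* **Escape hatch.** Real BLAST tabular output (12-column outfmt 6) can be
  injected anywhere through `read_blast_tab()` and the
  `forward_hits`/`reverse_hits` arguments of `assign_functions()`; query
  coverage, which BLAST does not emit, is recomputed from the aligned
  query span and a query-length table.

An implementation choice worth stating: the spec of the reciprocal search
leaves open whether the *second* pass also enforces the 60/80
identity/coverage thresholds. orthopath enforces them on both passes, so
"best filtered hit" means the same thing in both directions.

## Pathway assembly, gaps and validation

Annotated proteins are attached to template reactions by EC-number
intersection (a single shared EC suffices for multi-EC reactions);
function labels enter only through the template genes' EC sets. Reactions
with no attached protein are the *metabolic gaps* — they are reported,
never filled by threshold relaxation. `pathway_stats()` reports, per
sub-pathway, reaction/gap counts and the mean and median number of
distinct proteins per covered reaction, and per species the
template-gene and annotated-query counts (the "number of template
sequences / number of query sequences annotated" summary shape). Distinct
query proteins are counted once per species even when shared between
functions.

Validation aligns an experimentally supported protein set against the
annotated proteins; a known gene matches when its best alignment has
E ≤ 1e-10 and identity ≥ 90 (no coverage criterion — validation asks
whether the sequence exists, not whether it is a full-length ortholog).
Known genes must be supplied as protein sequences. The report includes the
fraction of validated annotations falling in regions B∪C, the diagnostic
that experimentally supported annotations should concentrate in the
high-confidence regions. Conserved-domain (motif) validation against the
NCBI CDD service is out of scope; its role is acknowledged but the package
provides no client for an external web service.

## Transcriptome overlay

Probe-to-gene mapping aligns each probe (as query, nucleotide mode)
against the gene sequences and keeps pairs with E ≤ 1e-10 and identity
≥ 95; a probe may represent several genes. Gene expression per condition
is the arithmetic mean over the gene's probes. The two-fold-change filter
is applied symmetrically — no condition is singled out as reference, so a
gene passes when `max(means) / max(min(means), 1) ≥ 2`; the denominator
floor of 1 signal unit guards against division by zero on dark probes.
Only passing genes are attached to the pathway graph (ordered condition
vectors per assigned protein, joined to proteins via the 12-digit
gene/transcript id convention when ids follow it). Microarray
normalisation and differential-expression statistics are out of scope:
the input is assumed already processed.

## The synthetic world

`generate_scenario()` states a controlled world in which every stage has a
known answer, recorded in a machine-readable truth manifest:

* **Ortholog families.** 30 families by default; each family has a random
  ancestor protein of 200–400 residues and per-branch orthologs mutated to
  an exact target identity drawn from 0.80–0.95 (substitutions only,
  BLOSUM-plausible replacements, exact mutation counts). Each family is
  present in 3–5 of the 5 template species, so `N_m` varies by design.
* **Decoys.** 30 unrelated random proteins (stated identity ceiling 0.30;
  in practice far lower), which must pass no filter.
* **Paralogs.** 5 families carry a query paralog derived from the query
  ortholog at 0.95 identity. Paralog families draw their branch
  identities from the top of the identity range, and the generator
  verifies — redrawing a bounded number of times if necessary — that each
  paralog sits strictly below its family's ortholog in identity to every
  template gene while staying above the filter floor. This makes the
  manifest exact: paralogs are predicted to be annotated as
  second-pass-confirmed evidence (`H = 0.5`), never as the RBH.
* **Clarity.** Each template gene is "unclear" with probability 0.2; its
  label gains a "putative" suffix and `F = 0.5`. Because function identity
  is label-based, putative labels form separate candidates — the manifest
  encodes the same grouping.
* **Gaps.** 3 families have no query ortholog at all, so their reactions
  must surface as metabolic gaps.
* **Transcripts and probes.** Query orthologs are back-translated with
  uniformly random synonymous codons; one 60-nt probe per gene is an exact
  transcript substring (additional probes carry one mismatch), plus 10
  unrelated decoy probes.
* **Expression.** Three root-type conditions (fibrous, developing,
  mature). Sucrose- and starch-synthesis families get a monotone
  increasing profile spanning 4.6-fold (mirroring the qualitative finding
  that pathway activity rises toward mature storage roots); Calvin-cycle
  families are flat controls spanning 1.15-fold and must fail the
  two-fold filter.

What a green end-to-end test establishes: threshold semantics, RBH logic,
evidence weighting, score arithmetic, gap detection, probe mapping and the
fold filter all behave exactly as specified under substitution-only
divergence with clean family separation. What it does not establish:
behaviour under indels, domain shuffling, genuine multi-gene families with
graded paralogy, compositional bias, or noisy expression — real data
properties the generator deliberately does not model.

## Numerical choices and degenerate inputs

* All threshold comparisons are inclusive, exactly as the critical values
  are printed (a hit at E = 1e-10, identity 60, coverage 80 survives).
* `CS = MS·N_m/N_t` holds to floating-point round-off; the region
  classifier tolerates one part in 10^9 on its domain checks so that
  scores computed through the identity cannot be rejected as invalid.
* Empty evidence is a usage error (unannotated ≠ score 0); an empty known
  set yields a warning and an empty report; an empty candidate table
  yields an empty, well-formed score table and an all-gap pathway with
  zero counts (no division by zero).
* Ties everywhere are broken deterministically (documented orderings), so
  identical inputs give byte-identical outputs; the run manifest records
  input checksums and configuration but no timestamps.

## Known limitations

* E-values are internally consistent but not BLAST-calibrated; when
  BLAST-grade statistics matter, import real BLAST tabular output.
* The engine is exact Smith–Waterman without heuristic seeding: suitable
  for pathway-scale gene sets (hundreds of sequences), not whole-proteome
  all-vs-all scans.
* One score per (protein, function) pair is computed; whether the original
  analysis scored per protein or per pair is not stated, and the per-pair
  choice is the more conservative (function-specific evidence lists).
* Region boundaries are tunable conventions, not calibrated statistics;
  no p-values or FDR are attached to MS/CS.
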