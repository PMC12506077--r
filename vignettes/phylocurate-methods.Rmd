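---
title: "Phylogeny-informed contamination removal: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-informed contamination removal: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocurate)
```

## The problem

Taxon-rich phylogenomic studies of microbial eukaryotes lean heavily on
single-cell and bulk transcriptomes, and such samples routinely carry
sequences from food organisms, hosts, co-cultured contaminants and bacteria.
Left in place, these sequences distort single-gene trees and, once
concatenated, species trees. `phylocurate` implements a transparent,
rule-driven workflow for removing them: the user writes down explicit,
publishable rules about which lineages a suspect taxon must not sit next to
in a gene tree, the package applies those rules iteratively, and every
removal is logged with the rule, iteration and observed tree context that
triggered it.

Everything keys on a controlled naming scheme. A taxon is a 10-character
code `MM_mm_Ssss`: a major clade (`Ba` Bacteria, `Za` Archaea, `Op`
Opisthokonta, `Am` Amoebozoa, `Ex` excavate lineages, `Sr` SAR, `Pl`
Archaeplastida, `EE` orphan lineages), a minor clade, and a species/sample
token — humans are `Op_me_Hsap`, *Arabidopsis thaliana* is `Pl_gr_Atha`.
A full sequence id prepends the taxon code to a free-form contig token
(which may embed assembler `length_` and `cov_` fields) and ends with a
gene-family token `OG6_` plus six digits. Parsing is greedy: first 10
characters are the taxon, the final `OG[6GA]_\d{6}` match is the gene
family, everything between is the contig. Each distinct 10-character code is
the counting unit everywhere; conspecific samples (`Am_tu_Hp01`,
`Am_tu_Hp02`) count separately, because any biological collapse of samples
into species is data-dependent and can be applied by the user upstream.

## The contamination loop

A run is an ordered schedule of phases, each phase a mode plus a rule list
plus an iteration budget. Within a phase the loop repeats
*build tree → root → apply rules → remove flagged leaves* until an iteration
removes nothing or the budget is exhausted. Tree rebuilding between
iterations is delegated to a callback so any external inference program can
be used; the built-in fallback prunes removed leaves from the gene family's
starting topology, which is deterministic and preserves the relationships
among the kept leaves exactly. (We chose pruning over a distance-based
rebuild because it introduces no model of its own; when sequences are
available, a user-supplied callback that truly re-infers trees is
preferable, and the loop accepts its stochasticity as documented.)

**Sister rules** remove a *single* sequence of a target lineage whose entire
pooled sister group matches one of the rule's forbidden prefixes. Two design
points matter:

* *Sole-target condition.* A rule fires only when the leaf is the sole
  target-matching leaf among its parent's leaf children. Two target leaves
  forming a cherry are co-contaminant territory, handled by subsister rules;
  this division keeps the two modes disjoint.
* *All-match condition.* Every sister-group taxon must match a forbidden
  prefix of the same rule. Mixed sister groups never fire a rule — a
  conservative choice that avoids removing sequences with partial
  conflicting signal.

Blanket rules (`branch_mode = "any"`) ignore branch lengths. Short-branch
rules additionally require the leaf's terminal branch to be shorter than
`multiplier` (default 0.5) times the tree's *average node-to-tip distance*.
We define that statistic as the mean terminal branch length over all leaves:
the quantity gates removal of an individual leaf, so the comparable
per-tree baseline is the distribution of terminal branches. A mean
root-to-tip depth variant is available via `avg_node_to_tip(mode =
"root_to_tip")` for users who prefer a depth-based scale.

**Subsister rules** remove a pair of sequences forming a cherry (one leaf
matching each pair member) whose joint sister group satisfies the forbidden
specification. Entries may be plain prefixes (every joint-sister leaf must
match one) or the complement form `non-X` (no joint-sister leaf may match
`X`), which expresses rules like "remove the pair when it falls sister to
non-Opisthokonta". Complements are supported only here, where they have a
concrete use.

**Clade grabbing** inverts the logic: instead of removing known-bad
neighbourhoods it retains only target sequences inside robust clades. A
clade qualifies when it contains at least `min_target` distinct target
codes, tolerating `nontarget_allowance` non-target codes (an absolute
count, or a fraction such as `"10%"` of the codes in the clade, rounded
down). Qualifying clades are *maximal*: no qualifying clade contains
another reported one. Target leaves outside every qualifying clade are
removed unless their taxon matches an exception prefix — the escape hatch
for orphan lineages that genuinely lack close relatives and would otherwise
always be discarded. Non-target leaves are never touched by this mode.

All rule firings within one iteration are evaluated against the frozen
input topology and applied together. This makes an iteration's outcome
independent of rule order and of the order leaves happen to be visited;
cascading effects (a removal exposing the next contaminant) are handled by
the next iteration, which is why phases iterate at all.

### Rooting

Sister relationships need a stable rooted frame. The default policy roots
on the edge subtending the largest pure-prokaryote (`Ba`/`Za`) clade,
evaluated over the unrooted split set, with ties broken by the
lexicographically smallest contained leaf label. We additionally require
that clade to have at least two leaves: when prokaryotes are reduced to
scattered singletons (itself a frequent symptom of contamination), a single
bacterial leaf is an unreliable anchor — and rooting on it can sit the root
directly on the terminal edge of a contaminant's neighbour, dissolving the
very sister pattern the rules test. In that case, and when no prokaryote is
present, the tree is midpoint rooted. Both branches are deterministic.

### Monophyly

`is_monophyletic()` asks whether some side of some bipartition of the
unrooted tree contains every target leaf with at most `allowed_interlopers`
non-target codes. Evaluating on splits rather than rooted clades makes the
answer invariant under re-rooting, which matters when comparing trees across
curation stages whose roots may differ. One consequence worth knowing: on a
three-leaf tree every two-leaf grouping is compatible with a bipartition,
so any pair is monophyletic there — non-monophyly first becomes expressible
with four leaves.

## Ortholog selection and concatenation

When a gene family holds several sequences of one taxon, the representative
is chosen in two steps. First, among all clades containing at least one of
the taxon's sequences, take the clade with the greatest number of distinct
taxon codes from the taxon's own minor clade — the "density of close
relatives" criterion; vertical orthologs sit among their relatives, while
contaminants and horizontal acquisitions sit elsewhere. Density ties prefer
the smallest clade, then the lexicographically smallest contained leaf, so
selection is a total order. (Counting at the major-clade level is available
via `clade_level = "major"` for sparsely sampled minor clades.) Second,
within the winning clade the taxon's sequence with the highest score wins:
score = residue length × k-mer coverage when the contig token carries
assembler coverage, otherwise just length — genome-derived CDSs have no
meaningful coverage.

`build_supermatrix()` concatenates one selected sequence per taxon per gene
family, filling absences with gaps, and records a 0-based half-open
partition map (also exported in RAxML's 1-based closed format).
`mask_gap_columns(threshold)` removes every column whose gap fraction is
**at or above** the threshold — the closed bound reads "at least 95%
gaps are removed" for the default 0.95; 0.50 is the stricter companion
setting. Masking is idempotent and masking at a loose then a tight
threshold equals masking once at the tight one.

## Composition-based curation

**GC3S** is the G+C fraction at third positions of codons from
synonymously variable families under the active genetic code: single-codon
families (Met, Trp in the standard code) and stops are excluded, a terminal
stop is trimmed, codons with ambiguity characters are skipped. It is
undefined (never imputed) when no eligible codon exists.

**ENc** (effective number of codons) follows Wright's estimator. Per
amino-acid family with \(n \ge 2\) observations, homozygosity is
\(F = (n\sum p_i^2 - 1)/(n-1)\); families are grouped by their degeneracy
class derived from the code table, and
\(N_c = N_1 + \sum_k N_k/\bar F_k\) with \(N_k\) the number of k-fold
families in the code (for the standard code: \(2 + 9/\bar F_2 + 1/\bar F_3
+ 5/\bar F_4 + 3/\bar F_6\)). Families observed fewer than twice are
excluded from their class average; a missing 3-fold class average is
replaced by \((\bar F_2 + \bar F_4)/2\); any other missing class leaves ENc
undefined. Values are capped at the sense-codon count (61), so exactly
uniform usage reports 61 and one-codon-per-family usage reports 20.
Degeneracy classes are always re-derived from the supplied code table, so
alternative nuclear codes are handled without special cases.

**GC classification** labels each sequence against its taxon's GC3S range:
inside (closed on both boundaries) keeps `OG6`, above becomes `OGG`
(GC-rich), below `OGA` (AT-rich), and the gene-family token in the emitted
id is rewritten accordingly. Ranges are user-supplied per taxon; deriving
them is out of scope here.

**Similarity filter.** Within one taxon and gene family, sequences are
visited in descending length order (ties: lexicographic id) and dropped
when their identity to an already-kept sequence reaches the cutoff (default
0.99). Identity is matches over aligned length under an ends-free global
alignment: internal gaps count against identity, terminal overhangs do not,
so a fragment is recognised as a duplicate of its full-length sibling. The
greedy order makes the kept set the longest representatives.

**Relative-length filter.** A sequence is kept iff its length lies in
\([m/3,\ 1.5m]\) (closed bounds) for its gene family's reference mean
length \(m\); sequences whose family has no reference mean are kept with a
warning rather than silently judged.

A homology-score cutoff of 0.3 ships in `default_config()` as the
hand-off value for an external alignment-confidence filter; no such filter
runs inside this package.

## The synthetic benchmark

`simulate_species_tree()` draws a random bifurcating tree over valid taxon
codes with every minor and major clade monophyletic in truth and
exponential branch lengths (mean 0.1 — substitutions/site on the order of
typical single-gene protein trees). `simulate_gene_trees()` derives each
gene tree from it by multiplicative log-normal branch noise (sd 0.25),
Bernoulli taxon dropout (default 0.1), optional within-taxon paralog
duplication, and planted contamination events:

* `sister_single` — one recipient-labelled leaf grafted as sole sister to a
  donor-clade leaf, terminal branch 0.2 × the tree's mean terminal branch
  (comfortably under the 0.5-multiplier threshold);
* `cherry_pair` — two recipients grafted as a cherry inside the donor clade;
* `misassigned_clade` — a pure block of recipient leaves inside the donor
  clade, emulating wholesale sample misassignment such as rumen-ciliate
  transcriptomes dominated by parabasalid sequences.

Events graft onto distinct, genuine donor leaves (never onto leaves planted
by earlier events), and dropout spares donor clades and recipients' minor
clades, so planted patterns are cleanly separated from sampling noise. This
is deliberate: the benchmark measures whether the loop's logic recovers
exactly the planted truth (recall 1.0, zero false removals), not how often
real gene-tree estimation error mimics contamination. Real data add
alignment error, model misspecification, incomplete lineage sorting and
genuine lateral transfer, none of which the generator emulates — a clean
pass here validates the machinery, not the biological error rate, and the
loop is documented to be capable of removing recent lateral transfers if
rules are aimed at them. One global seed fans out to per-gene-family seeds,
so any subset of families reproduces independently.

`simulate_cds()` draws stop-free coding sequences whose GC3S hits a target
by construction (the count of GC-ending third positions is fixed at
`round(target × n)`, positions randomised), with a `skew` knob
concentrating within-family codon choice to push ENc down. Realised GC3S
therefore deviates from target only by rounding, and the generated genes
double as an oracle fixture for the codon statistics.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately small,
fixed sizes chosen to exercise every code path while keeping the whole
suite near half a minute: brute-force oracle comparisons on 200 random
trees of 4–12 leaves (exhaustive per-node evaluation is quadratic and exact
at this size), a recovery study of 20 gene families over 34 taxa with 8
planted events of all three kinds, 50 seeded genes of 200–300 codons for
the codon statistics, and randomized supermatrices of 5 × ~20-column
partitions. Branch-length thresholds compare with strict `<`, as a removal
gate should; allowance fractions round down (`floor`) so "10% of 13" is 1;
degenerate inputs (no eligible codons, empty alignments, absent taxa,
fewer than three leaves) return defined errors or `NA` rather than guesses.

## Limitations

Rules are expert input: nothing here learns them from data, and a wrong
rule removes exactly what it names. Clade counting treats every distinct
code as a taxon; users wanting species-level counting must collapse samples
upstream. The loop's guarantees are per-iteration deterministic given the
rebuild callback's output; with a stochastic external tree builder, removed
sets can vary between runs, which the ledger makes visible rather than
hides. EGT flagging is a candidate screen with configurable thresholds
(minimum clade size 4, minimum interdigitated photosynthetic minor clades
3) and a user-supplied photosynthetic-lineage list — final calls need
manual inspection of the flagged trees.
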