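---
title: "Enrichment analysis of neuroimaging position and connection sets: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enrichment analysis of neuroimaging position and connection sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroenrich)
```

## The problem

Data-driven neuroimaging analyses routinely end with a large set of results
— thousands of voxels whose activity tracks a condition, or hundreds of
connections that differ between groups — and the interpretation step is too
often a subjective glance at which known brain networks the results "seem"
to overlap. `neuroenrich` replaces that step with the over-representation
machinery that is standard in genomics: given a background set of neural
positions, an annotation mapping positions to named classes (functional
networks, anatomic structures), and one or more identified sets of
positions or position pairs, it asks whether any class (or class pair) is
represented in the identified set significantly more than chance, with
explicit null models and multiple-testing control.

## Position group analysis

The background is a set $S$ of $M$ positions; a class $B \subseteq S$ has
capacity $K = |B \cap S|$; the identified group $A \subseteq S$ has size
$N$; the overlap is $x = |A \cap B|$. Under the null that the $N$ positions
were sampled uniformly without replacement from $S$, the significance of
the observed overlap is the hypergeometric upper tail, inclusive of $x$:

$$ p \;=\; \sum_{i=x}^{\min(N,K)}
   \frac{\binom{K}{i}\binom{M-K}{N-i}}{\binom{M}{N}}. $$

This is equivalent to a one-tailed Fisher exact test on the 2x2 table
$(x,\; N-x;\; K-x,\; M-K-N+x)$, and the package keeps
`fisher_one_tailed()` around purely as an independent oracle so the two
routes can be checked against each other.

Numerics: the sum is accumulated in log space from `lchoose()` terms
combined by log-sum-exp. Voxel-level studies produce p-values far below
double underflow (on the order of $10^{-300}$ and smaller), so every
result row retains `log10_p` alongside `p`; a `p` of exactly 0 in a report
is an underflow artifact, and downstream consumers (bar plots, reports)
fall back to the retained log record. Only over-representation is tested:
depletion has no tail here by design.

Each result also carries the *frequency ratio* $(x/N)/(K/M)$ — the class's
share of the tested set relative to its share of the background. It is a
descriptive effect size, not a significance measure; it is defined as 0
when $x = 0$, and classes with $K = 0$ after background restriction are
skipped rather than scored (both conventions are ours; the ratio's
behaviour at the boundary is otherwise undefined).

## Connection group analysis

Here the identified result is a set $A^c$ of unordered position pairs —
the edge set of a simple undirected graph $G(S, A^c)$ — and the classes of
interest are pairs of annotation classes $(C, D)$. The observed statistic
is $a(A^c, C, D)$, the number of edges with one endpoint in each class.
Two null models are available, and their disagreement is informative:

* **HG**: the $N$ edges were drawn uniformly from all
  $M = |S|(|S|-1)/2$ possible pairs, with pair capacity $K = |C||D|$
  (inter-class) or $K = |C|(|C|-1)/2$ (intra-class). The intra-class
  capacity is our extension: the source formulation defines $K$ only for
  disjoint $C \neq D$, but intra-network results are routinely of
  interest, and the triangular capacity is the natural count of possible
  within-class pairs.
* **DPP (degree-preserving permutation)**: the graph was drawn uniformly
  from all simple graphs with the same degree sequence as $G$. This null
  is sampled empirically with double-edge swaps (Maslov–Sneppen rewiring):
  two edges $(a,b), (c,d)$ are replaced by $(a,c),(b,d)$ or $(a,d),(b,c)$;
  proposals creating self-loops or duplicate edges are rejected without
  counting. Each of the $m$ samples (default 1000) is an independent chain
  of $10 \times |E|$ *successful* swaps started from the observed graph —
  standard rewiring practice; the chain length and independence of chains
  are our choices where the source says only "a long chain", and both are
  configurable via `dpp_config()`.

The empirical p-value is the fraction of null scores $\geq$ the observed
count, floored at $1/m$: a raw fraction of 0 would overstate certainty, and
$1/m$ is the smallest significance $m$ samples can support. Consequently
DPP p-values live on the grid $\{1/m, 2/m, \dots, 1\}$ and a larger $m$
buys resolution at linear cost.

HG is blind to the degree distribution; DPP conditions on it. On graphs
with exchangeable degrees the two agree asymptotically, and the test suite
checks this on near-uniform random graphs. They dissociate exactly where
brain networks live: if $C$ and $D$ sit on hubs, their edge count is
explained by degree alone and only HG calls enrichment; if $C$ and $D$
have low degree spent almost entirely on each other, DPP is the more
sensitive test.

Connection analysis requires pairwise-disjoint classes (a partition or
partial partition of the background): the capacity formula and the edge
counting are not well defined under overlap, so overlap is an input error
rather than a silent approximation. Position analysis has no such
restriction and tests overlapping classes independently.

### Determinism and seeding

DPP sampling is seeded counter-style from `(seed, stream, sample index)`,
where the stream separates the (group, class-pair) combinations of one
analysis. Identical configuration and seed give byte-identical reports;
samples are independent of evaluation order. Graphs that admit no valid
swap (a star: every edge shares the hub) are detected by a bounded number
of proposal attempts and returned unchanged with a "frozen graph" warning
— their null is degenerate and the empirical p is 1 by construction.

## Multiple testing

Every (group, class) or (group, class-pair) combination tested in one
invocation forms a single family; with both connection tests requested,
each test type is corrected as its own family, since the two p-value sets
answer the same question under different nulls and are reported side by
side. The default correction is Benjamini–Hochberg
($q_{(i)} = \min_{j \ge i} p_{(j)} \cdot n / j$, capped at 1), with
Bonferroni available. Declaring $q \le \alpha$ (default 0.05) controls the
FDR. With a five-class annotation a connection analysis therefore corrects
over $\binom{5}{2} + 5 = 15$ pairs per group per test. Published analyses
of this design differ in family size between their table and text by a
constant factor consistent with counting ordered rather than unordered
pairs; this package's family is the unordered one, stated here so results
can be compared knowingly.

## File conventions

Position ids are 1-based everywhere. Coordinate-file backgrounds number
positions by line. NIFTI volumes use the 1-based column-major linear index
of the voxel in the **full** volume as the id — restricted to the mask for
membership, but not renumbered — so a group volume and a background mask
with the same dimensions agree on ids with no mapping step. This is the
one place the design was genuinely open; renumbering `1..M` over the mask
was the alternative and would make ids depend on the mask, which breaks
mixed-format runs. Group volumes encode membership as positive integer
labels with 0 meaning "in no group"; the background is always a separate
input, never inferred from the group volume. MATLAB-exported inputs are
supported as plain-text numeric matrices with the same column semantics
(binary `.mat` is out of scope — no reader is available in this
dependency set). The NIFTI-1 reader/writer is minimal by intent (single
3D volume, common datatypes, sform/qform affine) and was cross-validated
against `nibabel` during development.

## The simulation harness

`run_implant_experiment()` regenerates the validation design used for the
method: base graphs of 244 nodes and 363 edges (or 1000 for the
high-degree variant) wired by a power-law scheme, a complete 5x5 biclique
implanted between random disjoint node sets $A, B$, each implanted edge
then removed independently with probability $q \in [0,1]$, and both tests
scored on the real pair $(A, B)$ and a dummy pair $(A', B')$.

Choices where the stated design was silent, made once and kept:

* *Generator*: "power law wiring scheme" is implemented Chung–Lu style —
  node weights $w_i \propto i^{-1/(\gamma-1)}$, endpoint pairs sampled
  with probability $\propto w_i w_j$, self-loops and duplicates rejected.
  This is the minimal-assumption reading; a configuration model or
  preferential attachment would also fit the phrase but add mechanics the
  validation does not need. The suite checks the operative property
  (heavier degree tails at $\gamma = 2$ than $\gamma = 3$), not a fitted
  exponent.
* *Implant semantics*: implanted edges are unioned with the base graph and
  noise removes only implanted edges, never base edges.
* *Dummy pair*: resampled each repetition in the random mode; in the
  high-degree mode it is the top-degree nodes outside $A \cup B$,
  the adversarial case where HG flags hub wiring as enrichment and DPP
  correctly does not.
* *Scale*: default 100 repetitions (the full design used 1000); at 100
  reps the qualitative claims tested — orders-of-magnitude real/dummy
  separation at $q = 0$, monotone decay with noise, the HG/DPP
  dissociation — are far outside Monte-Carlo error, and the suite stays
  inside a small CPU budget.

What a green simulation does **not** establish: the generator matches real
connectome degree sequences (it does not try to), the exact published
power curves (figure-only data, not reproduced numerically), or behaviour
under spatially autocorrelated signals — spatial nulls such as spin tests
are explicitly out of scope.

## Numerical and degenerate-input policy

* Hypergeometric parameters are validated against their invariants
  ($0 \le K \le M$, $0 \le N \le M$, $0 \le x \le \min(N,K)$); violations
  are parameter errors, never clamped.
* Ties in BH are handled by the running minimum; no special-casing.
* Duplicate connections collapse with a warning (real pipelines emit both
  orientations); self-connections are errors.
* Annotations are always restricted to the background before capacities
  are measured, so reported $K$ is $|B \cap S|$ regardless of annotation
  extras; positions dropped this way are counted in a message.
* Empty inputs (no groups, empty annotation, empty p-value family) are
  errors with specific messages rather than empty results.

## Known limitations

* The DPP sampler is a heuristic approximately-uniform sampler; on tiny
  null spaces its bias is measurable only as agreement with exhaustive
  enumeration (which the tests perform on the 4-cycle, where the exact
  null space has three graphs). No attempt is made at perfect uniform
  sampling.
* Only over-representation is tested; two-tailed and depletion questions
  need a different tail.
* Voxel-level integration against the published voxel case study requires
  data distributed only by its original authors and is therefore an
  optional external check, not part of the shipped suite; the parcel-level
  case-study dataset likewise could not be bundled (no network access in
  the build environment), so the corresponding acceptance test documents
  the expected file layout and fails informatively without it. A clearly
  synthetic 1024-parcel stand-in covers the same code paths in the
  regular suite.
* Weighted and directed graphs, surface formats, and upstream component
  discovery (e.g. the network-based statistic) are out of scope; this
  package consumes such output, it does not produce it.
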