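---
title: "Computing the inversion-indel distance between circular genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing the inversion-indel distance between circular genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invindel)
```

## The problem

Two unichromosomal circular genomes are compared as sequences of signed,
duplicate-free markers. Markers present in both genomes form the common set
$\mathcal{G}$; markers present in only one genome are *unique* to it. An
evolutionary scenario transforming genome $A$ into genome $B$ may use
**inversions** (reverse a contiguous segment and flip its signs) and
**indels** (insert or delete a contiguous block of markers), under two model
restrictions: common markers are never deleted, and insertions never create
duplicates. The *inversion-indel distance* $d_{INV}^{id}(A,B)$ is the length
of a shortest such scenario. This package computes it — exactly whenever the
structure of the comparison permits, and as a provable interval otherwise —
together with the intermediate quantities (DCJ distance, DCJ-indel distance,
equal-content inversion distance) that the theory builds on.

## The relational diagram

All computations start from the *relational diagram* $R(A,B)$. Each common
marker $g$ contributes two extremities, a tail $g^t$ and a head $g^h$; each
genome is drawn on a horizontal line with one vertex per extremity, laid out
in chromosome order after rotating (and, if necessary, reflecting) the circle
so that a chosen start marker comes first in direct orientation. Consecutive
extremity pairs on genome $A$'s line are joined by *orange* edges, on $B$'s
line by *blue* edges; each colored edge is labeled with the unique markers
lying between its two extremities (possibly none, a *clean* edge). Dotted
edges match equal extremities across the two lines. Every vertex has degree
two, so the diagram decomposes into cycles of length a multiple of four.

Walking each cycle (anchored, in this implementation, at its leftmost
upper-line vertex, first along the orange edge) assigns every colored edge a
traversal direction. Only *relative* directions matter; the anchor merely
makes the computation deterministic. With $c$ cycles, the DCJ distance —
inversions plus circular excision/reintegration — is
$$d_{DCJ}(A,B) = |\mathcal{G}| - c.$$

**Runs and indel-potential.** A *run* is a maximal subpath of a cycle whose
first and last edges are labeled and whose labeled edges all belong to one
genome; clean edges may sit inside a run, and run counting is cyclic (a color
block spanning the traversal anchor counts once). With $\Lambda(C)$ runs
(always $0$, $1$, or even), the *indel-potential*
$$\lambda(C) = \lceil (\Lambda(C)+1)/2 \rceil \quad (\lambda = 0
\text{ when } \Lambda = 0)$$
is the minimum number of indels to which the cycle's labels can be reduced
while sorting the cycle by splits, and
$$d_{DCJ}^{id}(A,B) = d_{DCJ}(A,B) + \sum_C \lambda(C).$$
The closed form is validated in the test suite against an exhaustive
split-DCJ minimization oracle (`min_runs_split_dcj()`) on cycles with
$\Lambda \le 4$.

## Components, good and bad

In the inversion-only model a cycle can be split only by an inversion acting
on two of its orange edges with *opposite* traversal directions. A
DCJ-unsorted cycle without such a pair is *bad*. Cycles interleave when each
has an orange edge strictly between two orange edges of the other; maximal
interleaving-connected sets of cycles are *components*, classified trivial
(a single 2-cycle), good (some good cycle), or bad. Bad components are the
only obstruction: without them the inversion distance equals the DCJ
distance, and the inversion-indel distance equals the DCJ-indel distance.
The latter equality is the package's central exact case, realized
constructively by `sort_no_bad()` and validated end-to-end against a
breadth-first-search oracle.

Because the genomes are circular and the diagram is a linearization, the
layout is rotated (over candidate start markers, in lexicographic order)
until, when two or more components exist, the first and last orange edges
lie in distinct components; spans, nesting, links, chains and separation are
then computed on that fixed linearization by their literal scan definitions
(quadratic, which is ample at the problem sizes this machinery targets).
Whether component classification can differ between admissible rotations is
not settled theory; the implementation fixes one rotation and relies on
oracle validation of the resulting distances.

## Singleton integrations and the exact case

Each run yields an *r-singleton*: the circular chromosome obtained by
concatenating the run's labels in run order. Integrating the singleton of a
$B$-run into $A$ (or of an $A$-run into $B$) at a site that creates a new
clean cycle is *optimal*: it preserves $d_{DCJ}$ and decreases
$\sum\lambda$ by exactly one. `optimal_integration_sites()` finds all such
sites by brute force — every rotation and orientation of the singleton at
every insertion site, each checked by rebuilding the diagram. This is a
deliberate design choice: the constructive mid-component argument for the
existence of a *safe* site (one whose result has no bad component) is only
sketched in the general nested case, so `safe_integration()` uses
search-plus-verification, and a missing safe site would surface as a loud
internal invariant error rather than a silently wrong answer. Repeating
safe integrations until no run remains yields the optimal integrated
completion $(A^*, B^*)$ with equal content, after which split inversions
chosen to keep the diagram free of bad components finish the scenario:
insertions first, then inversions, then deletions, of total length exactly
$d_{DCJ}^{id}$.

When processing runs the implementation takes them in diagram order,
integrating $B$-run singletons into $A$ and $A$-run singletons into $B$; the
choice is arbitrary in theory, and the pinned worked-example test instead
selects, among the optimal sites, the published intermediate genomes, which
the site enumeration always contains.

## Bad components: trees, covers, bounds

With bad components, extra inversions are needed: a *cut* (neutral
inversion, cost 1) makes one bad component good; a *merging* (joint
inversion, cost 2) merges two components — and every component separating
them — into one good component. The rooted *component tree* has a round
node per component (white = bad) and a square node per maximal chain of
linked components; its unrooted reduction $T'$ is the minimal subtree
containing all bad nodes. With $w$ leaves, the equal-content extra cost is
$$\tau_{INV} = w + 1 \text{ if } w \text{ is odd and every leaf is on a
long branch (a branch with} \ge 2 \text{ bad nodes)}, \quad w
\text{ otherwise},$$
where a leaf's branch is read up to, and excluding, the nearest node of
degree $\ge 3$ — the reading under which the closed form agrees with
exhaustive cover search on every instance the tests generate.

In the indel-aware model the costs of cuts and mergings change with the
runs of the affected cycles (`merge_cost()` tabulates them), and two
standing assumptions become reclassifications before the colored tree is
built: a bad component containing a cycle with $\ge 4$ runs can be cut at
zero net cost, and when two or more components contain a two-color cycle
they can all be merged at zero net cost — together with every component
separating a pair of them, since a merging also absorbs separators. The
package therefore treats all three kinds as good for the indel-aware
bounds; omitting the separator rule could push the reported lower bound
above the true distance, which the oracle sandwich test would reject.

On the colored reduction $T_o'$ (leaves carry the union of the colored dots
of their original subtree: orange for a component with an $A$-run, blue for
a $B$-run), a cover of the bad nodes by paths costs 1 per short path and 2
per long path — or 1 when the long path's endpoints share a dot. The
optimal cover cost is reported as the asserted-exact extra cost
$\tau_{INV}^{id}$, found by exhaustive search over partitions of the bad
nodes into path-coverable blocks (branch-and-bound, capped at 16
reduced-tree nodes; beyond the cap only the bounds are reported). No
polynomial algorithm is known for this cover, and the assertion that the
cover equals $\tau_{INV}^{id}$ is stated but not proven in the underlying
theory — so the report *always* carries the interval
$$d_{DCJ}^{id} + \lceil w/2 \rceil \;\le\; d_{INV}^{id} \;\le\;
d_{DCJ}^{id} + w + 1,$$
alongside any point value, and the test suite checks the
breadth-first-search oracle against the interval, not the point value.

Fewer than two common markers makes sorting trivial: delete the unique
content of $A$ at once, insert the unique content of $B$ at once. The
distance is therefore 0, 1 or 2, counting nonempty unique contents — the
only reading consistent with block indels.

## The synthetic generator

`random_genome_pair(n_common, n_inversions, n_uniqueA, n_uniqueB)` draws
$B$ as the identity $(g_1 \dots g_n)$, applies uniformly random inversions
to obtain $A$, and inserts unique markers with random signs at uniform
positions into both; `require_no_bad` rejection-samples until the diagram
has no bad component. All randomness flows through R's RNG, and an explicit
`seed` restores the caller's RNG state afterwards.

The generator emulates the combinatorial structure the theory addresses —
signed circular gene orders of unequal content — and nothing else: no
marker-length variation, no rate heterogeneity along the chromosome, no
duplications, no linear chromosomes. Passing tests therefore certify the
combinatorial machinery, not any statistical fit to real gene orders.
Because uniformly random signed genomes rarely produce bad components, the
test suite supplements the generator with unsigned permutations (all
markers in direct orientation), which produce bad components in the large
majority of draws and exercise the component-tree path.

## Numerical and design choices

* **Start marker and anchors.** Lexicographically smallest common marker;
  cycle traversal anchored at the leftmost upper-line vertex. Both choices
  only fix representatives of symmetry classes.
* **Genome equality** includes reflection (reading the circle backwards
  with flipped signs), so the search oracles see one state per genome.
* **Composite markers.** `collapse_unique_blocks()` gives composites
  reserved `__blk` names that the parser refuses in user input, preventing
  collisions; per-cycle run counts are unchanged by collapsing (tested).
* **Oracle depth caps** default to crude bounds independent of the theory
  under test (`|A| + |B| + 2` for the indel search); a cap hit raises an
  error instead of returning a value. The indel oracle searches
  bidirectionally — every move is invertible with the roles of the genomes
  swapped — purely as an engineering measure; move semantics are unchanged.
* **Problem sizes.** The validation suites run at up to 6 common markers
  (inversion oracle), 5 (DCJ oracle) and 4 common plus 2 unique markers per
  genome (indel oracle), with 100–200 replicates per property; these sizes
  keep every brute-force state space exactly enumerable.
* **Degenerate inputs.** Single-marker genomes are legal; equal genomes
  give empty scenarios; deletion of an entire genome is rejected
  (model-violation error), as are linear (`$`-terminated) records.

## Known limitations

The exact value of $\tau_{INV}^{id}$ in the presence of bad components is an
open problem; the package reports the exhaustive cover cost as
asserted-exact only, always alongside the proven interval. Linear and
multichromosomal genomes, duplicated markers and non-unit indel costs are
out of scope. The component machinery is quadratic-to-cubic and intended
for desk-scale analyses (tens of markers), not genome-scale scans.

## A worked session

```{r example}
A <- parse_genome("(a x -c y b -z -d)")
B <- parse_genome("(a u b c v d)")
fit <- inv_indel(A, B)
fit

sc <- sort_no_bad(A, B)
sc
replay_scenario(sc)
```
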