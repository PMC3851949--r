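# invindel

Genome rearrangement distances between unichromosomal **circular genomes
with unequal marker content** and no duplicated markers, in the
inversion-indel model: inversions of contiguous segments plus insertions
and deletions of contiguous marker blocks, where common markers may never
be deleted and insertions never create duplicates.

The package is aimed at researchers in comparative genomics and molecular
evolution who want exact, fully checkable distance computations and sorting
scenarios at desk scale — for teaching, for validating heuristics, or for
analyzing small genomes (organelles, viruses, synthetic constructs)
represented as signed gene orders.

## The model in brief

For genomes *A* and *B* with common marker set 𝒢, the *relational diagram*
R(A,B) places one vertex per marker extremity per genome on two parallel
lines; colored edges join consecutive extremities and carry the unique
markers between them as labels; dotted edges match extremities across
genomes. The diagram is a disjoint union of cycles, and with *c* cycles:

* **DCJ distance** (double cut and join): `d_DCJ = |𝒢| − c`.
* **DCJ-indel distance**: `d_DCJ^id = d_DCJ + Σ_C λ(C)`, where the
  *indel-potential* of a cycle with Λ runs of same-genome labels is
  `λ = ⌈(Λ+1)/2⌉` (0 for a clean cycle).
* **Inversion distance** (equal content): `d_INV = d_DCJ + τ_INV`, with
  `τ_INV` computed from the reduced component tree (*w* leaves; `w + 1` if
  *w* is odd and every leaf is on a long branch, else *w*).
* **Inversion-indel distance**: when R(A,B) has no *bad component* (a
  component none of whose cycles can be split by an inversion),
  `d_INV^id = d_DCJ^id` **exactly**, realized by safe integrations of run
  singletons followed by split inversions. With bad components the package
  reports the interval
  `d_DCJ^id + ⌈w/2⌉ ≤ d_INV^id ≤ d_DCJ^id + w + 1`
  and narrows it with an exhaustive colored-cover search over the
  component tree (asserted-exact; the exact formula is an open problem).

Everything is validated in the test suite against brute-force
breadth-first-search oracles on small instances: inversion-only, DCJ, and
full inversion-indel search, plus an exhaustive split-DCJ minimization that
certifies the indel-potential formula.

## A worked example

```r
library(invindel)
A <- parse_genome("(a x -c y b -z -d)")
B <- parse_genome("(a u b c v d)")
inv_indel(A, B)
#> Inversion-indel distance report
#>   markers: 4 common, 3 only in A, 2 only in B
#>   cycles c = 1, sum of indel-potentials = 3
#>   d_DCJ = 3, d_DCJ-indel = 6
#>   bad components: 0 (w = 0 after reclassification)
#>   d_INV-indel = 6 (exact: no bad component)
```

The single diagram cycle has Λ = 4 runs, so λ = 3: three block indels are
unavoidable, and with no bad component the 6-step distance (3 DCJ + 3
indels) is exact. A witness scenario:

```r
sort_no_bad(A, B)
#> Sorting scenario: 6 step(s) from (a x -c y b -z -d) to (a u b c v d)
#>    1. INS (v) after z
#>    2. INS (u) after a
#>    3. INV cut sites 0..8
#>    4. INV cut sites 1..5
#>    5. INV cut sites 2..4
#>    6. DEL (x z y)
```

Two insertions bring in *B*'s unique markers at their optimal sites, three
inversions sort the completed genomes, and one deletion removes *A*'s
unique markers (accumulated into a single block by the inversions). With
bad components the report keeps the proven interval instead:

```r
A2 <- parse_genome("(a w -d -c y b -z -e f x i j h g)")
B2 <- parse_genome("(a s b c d u v e f g h i t j r)")
inv_indel(A2, B2)
#> Inversion-indel distance report
#>   markers: 10 common, 4 only in A, 5 only in B
#>   cycles c = 5, sum of indel-potentials = 6
#>   d_DCJ = 5, d_DCJ-indel = 11
#>   bad components: 1 (w = 1 after reclassification)
#>   d_INV-indel in [12, 13]; optimal colored cover gives 12
```

A thin command-line front end ships at `inst/cli/invindel.R`
(`Rscript inst/cli/invindel.R dist A.txt B.txt --model dcj`, plus
`diagram`, `components`, `tree`, `sort`, `simulate` and `oracle`
subcommands over genome files in parenthesized or GRIMM circular notation).

See `vignettes/inversion-indel-distance.Rmd` for the full account of the
diagram, runs, component trees, covers and the design decisions.

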