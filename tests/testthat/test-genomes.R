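test_that("parsing accepts both notations and preserves order and signs", {
  g <- fig2_A()
  expect_length(g$markers, 14L)
  expect_identical(sum(g$signs < 0L), 4L)
  expect_identical(g$markers[1:4], c("a", "w", "d", "c"))

  expect_length(parse_genome("(a)")$markers, 1L)

  grimm <- parse_genome("a -b @")
  expect_true(genomes_equal(grimm, genome(c("a", "-b"))))

  withhdr <- parse_genome(">mygenome\n(a b c)")
  expect_identical(withhdr$label, "mygenome")
})

test_that("parsing rejects malformed records", {
  expect_error(parse_genome("(a b a)"), class = "invindel_duplicate_marker")
  expect_error(parse_genome("( )"), class = "invindel_format")
  expect_error(parse_genome("a b $"), class = "invindel_unsupported_structure")
  expect_error(parse_genome("(a __blkA1)"), class = "invindel_format")
  expect_error(parse_genome("a b"), class = "invindel_format")
})

test_that("genome records round-trip through write/parse", {
  g <- fig2_A()
  g$label <- "A"
  expect_true(genomes_equal(parse_genome(write_genome(g)), g))
  expect_true(genomes_equal(parse_genome(write_genome(g, format = "grimm")), g))
  expect_identical(parse_genome(write_genome(g))$markers, g$markers)
})

test_that("canonical form identifies rotations and reflections", {
  expect_identical(canonical_form(genome(c("b", "a"))),
                   canonical_form(genome(c("a", "b"))))
  expect_identical(canonical_form(genome(c("a", "-b"))),
                   canonical_form(genome(c("b", "-a"))))
  # the three printed representations of the same circular genome
  r1 <- parse_genome("(a w -d -c y b -z -e f x i j h g)")
  r2 <- parse_genome("(c d -w -a -g -h -j -i -x -f e z -b -y)")
  r3 <- parse_genome("(y b -z -e f x i j h g a w -d -c)")
  expect_identical(canonical_form(r1), canonical_form(r2))
  expect_identical(canonical_form(r1), canonical_form(r3))
})

test_that("canonical form is idempotent and invariant under random rotation/reflection", {
  set.seed(101)
  for (k in 1:25) {
    p <- random_genome_pair(sample(2:6, 1), sample(0:3, 1),
                            sample(0:2, 1), 0)
    g <- p$A
    cf <- canonical_form(g)
    expect_identical(canonical_form(genome(cf)), cf)
    rot <- invindel:::rotate_genome(g, sample(length(g$markers), 1))
    expect_identical(canonical_form(rot), cf)
    expect_identical(canonical_form(invindel:::reflect_genome(g)), cf)
  }
})

test_that("marker classification matches the worked example and is symmetric", {
  part <- classify_markers(fig2_A(), fig2_B())
  expect_identical(part$common, sort(c("a","b","c","d","e","f","g","h","i","j")))
  expect_identical(part$onlyA, c("w", "x", "y", "z"))
  expect_identical(part$onlyB, c("r", "s", "t", "u", "v"))

  g <- genome(c("a", "b"))
  same <- classify_markers(g, g)
  expect_length(same$onlyA, 0L)
  expect_length(same$onlyB, 0L)

  disj <- classify_markers(genome("a"), genome("b"))
  expect_length(disj$common, 0L)

  sw <- classify_markers(fig2_B(), fig2_A())
  expect_identical(sw$onlyA, part$onlyB)
  expect_identical(sw$onlyB, part$onlyA)
  expect_identical(sw$common, part$common)
})

test_that("operations transform genomes as the rearrangement model specifies", {
  A <- fig2_A()
  # invert the segment "y b" (positions 5..6)
  inv <- apply_operation(A, inversion_op(4L, 6L))
  expect_true(genomes_equal(
    inv, parse_genome("(a w -d -c -b -y -z -e f x i j h g)")))

  B <- fig2_B()
  del <- apply_operation(B, deletion_op(c("u", "v")),
                         common = classify_markers(fig2_A(), B)$common)
  expect_true(genomes_equal(del, parse_genome("(a s b c d e f g h i t j r)")))

  # inverting a full-genome segment reflects the circle: an equal genome
  full <- apply_operation(A, inversion_op(0L, length(A$markers)))
  expect_true(genomes_equal(full, A))

  ins <- apply_operation(genome(c("a", "b")), insertion_op(c("-u"), "a"))
  expect_true(genomes_equal(ins, genome(c("a", "-u", "b"))))
})

test_that("operations enforce the indel restrictions", {
  B <- fig2_B()
  common <- classify_markers(fig2_A(), B)$common
  expect_error(apply_operation(B, deletion_op(c("d", "u")), common = common),
               class = "invindel_model_violation")
  expect_error(apply_operation(B, deletion_op(c("s", "u"))),
               class = "invindel_model_violation")   # not contiguous
  expect_error(apply_operation(B, insertion_op("a", "b")),
               class = "invindel_model_violation")   # duplicate
})

test_that("an inversion is an involution", {
  set.seed(7)
  for (k in 1:20) {
    p <- random_genome_pair(sample(2:6, 1), sample(0:4, 1), sample(0:2, 1), 0)
    g <- p$A
    n <- length(g$markers)
    s <- sort(sample(0:n, 2L))
    if (s[1] == s[2]) next
    op <- inversion_op(s[1], s[2])
    expect_true(genomes_equal(apply_operation(apply_operation(g, op), op), g))
  }
})

test_that("collapsing unique blocks preserves the diagram's run structure", {
  cc <- collapse_unique_blocks(fig2_A(), fig2_B())
  # the block "u v" of B becomes one composite marker
  expect_true(any(startsWith(cc$B$markers, "__blkB")))
  expect_identical(cc$map[["__blkB1"]], c("u", "v"))
  expect_true(genomes_equal(expand_blocks(cc$B, cc$map), fig2_B()))

  # no adjacent unique pair: returned unchanged (up to rotation)
  A <- genome(c("a", "x1", "b", "c"))
  B <- genome(c("a", "b", "y1", "c"))
  cc2 <- collapse_unique_blocks(A, B)
  expect_true(genomes_equal(cc2$A, A))
  expect_true(genomes_equal(cc2$B, B))
  expect_length(cc2$map, 0L)

  set.seed(42)
  for (k in 1:60) {
    p <- random_genome_pair(sample(3:6, 1), sample(0:3, 1),
                            sample(0:3, 1), sample(0:3, 1))
    R1 <- build_diagram(p$A, p$B)
    cc <- collapse_unique_blocks(p$A, p$B)
    R2 <- build_diagram(cc$A, cc$B)
    expect_identical(sort(vapply(R1$cycles, `[[`, integer(1), "Lambda")),
                     sort(vapply(R2$cycles, `[[`, integer(1), "Lambda")))
    expect_true(all(vapply(R2$cycles, function(cy)
      all(lengths(cy$labels) <= 1L), logical(1))))
    expect_true(genomes_equal(expand_blocks(cc$A, cc$map), p$A))
    expect_true(genomes_equal(expand_blocks(cc$B, cc$map), p$B))
  }
})

test_that("the generator is seeded, self-consistent and honors its flags", {
  p1 <- random_genome_pair(6, 3, 2, 2, seed = 77)
  p2 <- random_genome_pair(6, 3, 2, 2, seed = 77)
  expect_identical(p1, p2)

  p0 <- random_genome_pair(5, 0, 0, 0, seed = 1)
  expect_true(genomes_equal(p0$A, p0$B))

  set.seed(9)
  for (k in 1:60) {
    nc <- sample(2:6, 1); ua <- sample(0:3, 1); ub <- sample(0:3, 1)
    p <- random_genome_pair(nc, sample(0:4, 1), ua, ub)
    expect_false(anyDuplicated(p$A$markers) > 0)
    expect_false(anyDuplicated(p$B$markers) > 0)
    part <- classify_markers(p$A, p$B)
    expect_length(part$common, nc)
    expect_length(part$onlyA, ua)
    expect_length(part$onlyB, ub)
  }

  set.seed(10)
  for (k in 1:30) {
    p <- random_genome_pair(sample(3:6, 1), sample(0:4, 1),
                            sample(0:2, 1), sample(0:2, 1),
                            require_no_bad = TRUE)
    expect_false(has_bad(p$A, p$B))
  }
})
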