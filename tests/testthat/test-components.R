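test_that("interleaving matches the worked example and excludes 2-cycles", {
  R2 <- build_diagram(fig2_A(), fig2_B())
  small_bad <- Filter(function(cy) cy$n_orange == 2L, R2$cycles)
  expect_length(small_bad, 2L)
  expect_true(interleaving(small_bad[[1]], small_bad[[2]]))

  two_cycles <- Filter(function(cy) cy$n_orange == 1L, R2$cycles)
  for (cy in R2$cycles) {
    if (cy$id != two_cycles[[1]]$id)
      expect_false(interleaving(two_cycles[[1]], cy))
  }
  expect_error(interleaving(two_cycles[[1]], two_cycles[[1]]),
               class = "invindel_not_applicable")
})

test_that("the worked example decomposes into its four components", {
  R2 <- build_diagram(fig2_A(), fig2_B())
  comps <- find_components(R2)
  expect_length(comps, 4L)
  expect_identical(sort(vapply(comps, `[[`, character(1), "class")),
                   c("bad", "good", "trivial", "trivial"))
  bad <- comps[[which(vapply(comps, `[[`, character(1), "class") == "bad")]]
  expect_length(bad$cycles, 2L)
  # the bad component has an orange and a blue dot (runs x and r)
  expect_identical(bad$dots, c("A", "B"))
})

test_that("identity genomes give only trivial components", {
  id <- genome(letters[1:5])
  comps <- find_components(build_diagram(id, id))
  expect_true(all(vapply(comps, `[[`, character(1), "class") == "trivial"))
})

test_that("the no-bad generator flag agrees with component classification", {
  set.seed(13)
  for (k in 1:50) {
    p <- random_genome_pair(sample(3:6, 1), sample(0:5, 1),
                            sample(0:2, 1), sample(0:2, 1),
                            require_no_bad = TRUE)
    comps <- find_components(build_diagram(p$A, p$B))
    expect_false(any(vapply(comps, `[[`, character(1), "class") == "bad"))
  }
})

test_that("separation in the worked example matches the published reading", {
  nd <- normalized_diagram(fig2_A(), fig2_B())
  comps <- nd$components
  rel <- component_relations(comps, nd$R)
  cls <- vapply(comps, `[[`, character(1), "class")
  sizes <- vapply(comps, function(k) length(k$cycles), integer(1))
  good_id <- which(cls == "good")
  bad_id <- which(cls == "bad")
  triv <- which(cls == "trivial")
  # the trivial component nested inside the good one vs the one inside the bad
  t_in_good <- triv[rel$parent[triv] == good_id]
  t_in_bad <- triv[rel$parent[triv] == bad_id]
  seps <- rel$separations
  sep_holds <- function(s, a, b) {
    any(seps$separator == s &
          ((seps$c1 == a & seps$c2 == b) | (seps$c1 == b & seps$c2 == a)))
  }
  # the good component separates the nested trivial one from both others
  expect_true(sep_holds(good_id, t_in_good, t_in_bad))
  expect_true(sep_holds(good_id, t_in_good, bad_id))
  # the bad component separates its nested trivial one from both others
  expect_true(sep_holds(bad_id, t_in_bad, t_in_good))
  expect_true(sep_holds(bad_id, t_in_bad, good_id))
})

test_that("a single component has empty relations", {
  nd <- normalized_diagram(fig4_A(), fig4_B())
  rel <- component_relations(nd$components, nd$R)
  expect_identical(nrow(rel$links), 0L)
  expect_identical(nrow(rel$separations), 0L)
  expect_length(rel$chains, 1L)
  expect_true(is.na(rel$parent[1]))
})

test_that("nesting is a strict partial order on random diagrams", {
  set.seed(19)
  for (k in 1:30) {
    p <- if (k %% 2L) random_genome_pair(sample(4:7, 1), sample(1:5, 1),
                                         sample(0:2, 1), sample(0:2, 1))
         else random_unsigned_pair(sample(4:7, 1))
    nd <- normalized_diagram(p$A, p$B)
    nst <- component_relations(nd$components, nd$R)$nested
    m <- nrow(nst)
    if (m < 2L) next
    expect_false(any(nst & t(nst)))                 # antisymmetric
    for (i in seq_len(m)) for (j in seq_len(m)) for (l in seq_len(m)) {
      if (nst[i, j] && nst[j, l]) expect_true(nst[i, l])   # transitive
    }
  }
})

test_that("a joint inversion merges components and separators into one good component", {
  set.seed(23)
  merged_cases <- 0L
  for (k in 1:40) {
    p <- if (k %% 2L) random_genome_pair(sample(4:7, 1), sample(1:5, 1))
         else random_unsigned_pair(sample(5:7, 1))
    nd <- normalized_diagram(p$A, p$B)
    comps <- nd$components
    if (length(comps) < 2L) next
    R <- nd$R
    rel <- component_relations(comps, R)
    rotA <- R$lineA$genome
    # pick one orange edge in each of two distinct components
    i <- comps[[1]]$pos[length(comps[[1]]$pos)]
    j <- comps[[2]]$pos[1]
    if (i >= j) next
    A2 <- apply_operation(rotA, inversion_op(i, j))
    R2 <- build_diagram(A2, p$B, start = R$start)
    expect_identical(length(R2$cycles), length(R$cycles) - 1L)
    # track preserved adjacencies by marker-name pairs
    adj_names <- function(Rx, e) {
      ord <- Rx$lineA$order$name
      sort(c(ord[e], ord[e %% Rx$n + 1L]))
    }
    comps2 <- find_components(R2)
    edge_comp2 <- function(pair) {
      for (cc in comps2) for (e in cc$pos) {
        if (identical(adj_names(R2, e), pair)) return(cc$id)
      }
      NA_integer_
    }
    # the merged adjacency at site i now sits in a good component
    merged_id <- edge_comp2(sort(c(R$lineA$order$name[i], A2$markers[
      match(R$lineA$order$name[i], A2$markers) %% length(A2$markers) + 1L])))
    if (is.na(merged_id)) next
    expect_identical(comps2[[merged_id]]$class, "good")
    # every component separating the two merged ones joins the new component
    seps <- rel$separations
    sel <- seps$separator[(seps$c1 == 1L & seps$c2 == 2L) |
                            (seps$c1 == 2L & seps$c2 == 1L)]
    for (s in sel) {
      for (e in comps[[s]]$pos) {
        if (e > i && e <= j) next   # edge layout moved by the inversion
        expect_identical(edge_comp2(adj_names(R, e)), merged_id)
      }
    }
    merged_cases <- merged_cases + 1L
  }
  expect_gt(merged_cases, 5L)
})
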