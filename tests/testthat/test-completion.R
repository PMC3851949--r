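test_that("singleton extraction walks runs in label order", {
  R4 <- build_diagram(fig4_A(), fig4_B())
  ss <- extract_singletons(R4)
  expect_length(ss, 4L)   # the single cycle has four runs
  contents <- vapply(ss, function(s) paste(s$content, collapse = " "),
                     character(1))
  expect_true("z y" %in% contents)
  expect_true("x" %in% contents)

  id <- genome(letters[1:3])
  expect_length(extract_singletons(build_diagram(id, id)), 0L)

  R2 <- build_diagram(fig2_A(), fig2_B())
  total_runs <- sum(vapply(R2$cycles, `[[`, integer(1), "Lambda"))
  expect_length(extract_singletons(R2), total_runs)
})

test_that("the printed completion of the worked example is reproducible", {
  A <- fig4_A(); B <- fig4_B()
  R <- build_diagram(A, B)
  expect_identical(length(R$cycles), 1L)

  ss <- extract_singletons(R)
  zy <- Filter(function(s) s$side == "A" &&
                 identical(sort(s$content), c("y", "z")), ss)[[1]]
  sites <- optimal_integration_sites(zy, B, A)
  hit <- Filter(function(st)
    genomes_equal(st$result, parse_genome("(a u b c v d z y)")), sites)
  expect_gt(length(hit), 0L)
  B1 <- hit[[1]]$result
  expect_identical(length(build_diagram(A, B1)$cycles), 3L)

  ss2 <- extract_singletons(build_diagram(A, B1))
  vu <- Filter(function(s) s$side == "B", ss2)[[1]]
  sites2 <- optimal_integration_sites(vu, A, B1)
  hit2 <- Filter(function(st)
    genomes_equal(st$result, parse_genome("(a x -c y b -z -d -v u)")), sites2)
  expect_gt(length(hit2), 0L)
  A1 <- hit2[[1]]$result
  expect_identical(length(build_diagram(A1, B1)$cycles), 5L)

  ss3 <- extract_singletons(build_diagram(A1, B1))
  x <- Filter(function(s) s$side == "A", ss3)[[1]]
  sites3 <- optimal_integration_sites(x, B1, A1)
  hit3 <- Filter(function(st)
    genomes_equal(st$result, parse_genome("(a x u b c v d z y)")), sites3)
  expect_gt(length(hit3), 0L)
  Rf <- build_diagram(A1, hit3[[1]]$result)
  expect_identical(length(Rf$cycles), 6L)
  expect_true(all(vapply(Rf$cycles, function(cy) cy$Lambda == 0L, logical(1))))
  expect_identical(length(Rf$cycles) - length(R$cycles), 5L)
  # the DCJ distance is preserved by the completion
  expect_identical(Rf$n - length(Rf$cycles), R$n - length(R$cycles))
})

test_that("every optimal integration decrements the total indel-potential", {
  set.seed(61)
  for (k in 1:12) {
    p <- random_genome_pair(sample(3:5, 1), sample(0:2, 1),
                            sample(1:2, 1), sample(1:2, 1))
    R <- build_diagram(p$A, p$B)
    ss <- extract_singletons(R)
    if (!length(ss)) next
    s <- ss[[1]]
    target <- if (s$side == "B") p$A else p$B
    other <- if (s$side == "B") p$B else p$A
    sites <- optimal_integration_sites(s, target, other)
    expect_gt(length(sites), 0L)
    sl0 <- invindel:::sum_lambda(R)
    d0 <- R$n - length(R$cycles)
    for (st in sites[seq_len(min(3L, length(sites)))]) {
      R1 <- build_diagram(st$result, other)
      expect_identical(invindel:::sum_lambda(R1), sl0 - 1L)
      expect_identical(R1$n - length(R1$cycles), d0)
    }
  }
})

test_that("an optimal integration may be unsafe, but a safe one always exists", {
  A <- fig5_A(); B <- fig5_B()
  s <- Filter(function(s) s$side == "B",
              extract_singletons(build_diagram(A, B)))[[1]]
  expect_length(s$content, 3L)
  sites <- optimal_integration_sites(s, A, B)
  unsafe <- vapply(sites, function(st) has_bad(st$result, B), logical(1))
  expect_true(any(unsafe))        # the published counterexample site
  expect_true(any(!unsafe))
  chosen <- safe_integration(s, A, B)
  expect_false(has_bad(chosen$result, B))

  set.seed(67)
  for (k in 1:25) {
    p <- random_genome_pair(sample(2:4, 1), sample(0:2, 1),
                            sample(0:2, 1), sample(0:2, 1),
                            require_no_bad = TRUE)
    ss <- extract_singletons(build_diagram(p$A, p$B))
    if (!length(ss)) next
    s <- ss[[1]]
    target <- if (s$side == "B") p$A else p$B
    other <- if (s$side == "B") p$B else p$A
    chosen <- safe_integration(s, target, other)
    expect_false(has_bad(chosen$result, other))
  }
})

test_that("integrated completion performs exactly sum-lambda steps and ends clean", {
  cc <- integrated_completion(fig4_A(), fig4_B())
  expect_length(cc$steps, 3L)
  Rf <- build_diagram(cc$A_star, cc$B_star)
  expect_true(all(vapply(Rf$cycles, function(cy) cy$Lambda == 0L, logical(1))))

  id <- genome(letters[1:3])
  cc0 <- integrated_completion(id, id)
  expect_length(cc0$steps, 0L)
  expect_true(genomes_equal(cc0$A_star, id))

  set.seed(71)
  for (k in 1:10) {
    p <- random_genome_pair(sample(2:4, 1), sample(0:2, 1),
                            sample(0:2, 1), sample(0:2, 1),
                            require_no_bad = TRUE)
    sl <- invindel:::sum_lambda(build_diagram(p$A, p$B))
    cc <- integrated_completion(p$A, p$B)
    expect_length(cc$steps, sl)   # internal stopifnot checks the rest
  }
})

test_that("sorting scenarios replay to the target at the exact distance", {
  A <- genome(letters[1:4])
  sc0 <- sort_no_bad(A, A)
  expect_identical(sc0$length, 0L)

  sc4 <- sort_no_bad(fig4_A(), fig4_B())
  expect_identical(sc4$length, 6L)
  replay_scenario(sc4)

  # one common marker: trivial delete-then-insert scenario
  sc1 <- sort_no_bad(genome(c("a", "x", "y")), genome(c("a", "u")))
  expect_identical(sc1$length, 2L)
  replay_scenario(sc1)

  set.seed(73)
  for (k in 1:12) {
    p <- random_genome_pair(sample(2:4, 1), sample(0:2, 1),
                            sample(0:2, 1), sample(0:2, 1),
                            require_no_bad = TRUE)
    sc <- sort_no_bad(p$A, p$B)
    replay_scenario(sc)
    fit <- inv_indel(p$A, p$B)
    expect_identical(sc$length, fit$d_inv_indel)
    kinds <- vapply(sc$ops, `[[`, character(1), "kind")
    expect_false(is.unsorted(match(kinds,
                                   c("insertion", "inversion", "deletion"))))
  }
})

test_that("sorting refuses diagrams with bad components", {
  A <- genome(c("g1", "g3", "g2"))
  B <- genome(c("g1", "g2", "g3"))
  expect_true(has_bad(A, B))
  expect_error(sort_no_bad(A, B), class = "invindel_wrong_precondition")
})
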