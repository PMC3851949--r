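# Runs -> circular singletons, optimal and safe integrations, the optimal
# integrated completion (A*, B*), and sorting-scenario generation when the
# diagram has no bad component.

#' Extract the r-singletons of a diagram
#'
#' One circular singleton per run: its content is obtained by walking the
#' run's path and concatenating its labels in run order (the circle closes
#' from the last label back to the first).
#'
#' @param R A [build_diagram()] result.
#' @return List of singletons, each with `cycle` (cycle id), `side` (`"A"`
#'   for an A-run, `"B"` for a B-run), `content` (signed tokens) and `m`
#'   (number of labels in the run).
#' @export
extract_singletons <- function(R) {
  out <- list()
  for (cy in R$cycles) {
    for (r in cy$runs) {
      out[[length(out) + 1L]] <- list(cycle = cy$id, side = r$side,
                                      content = r$content, m = r$m)
    }
  }
  out
}

has_bad_component <- function(A, B) {
  comps <- find_components(build_diagram(A, B))
  any(vapply(comps, function(k) k$class == "bad", logical(1)))
}

#' All optimal integration sites of a singleton
#'
#' An integration of an r-singleton into the chromosome of the other genome
#' is optimal when it creates a new clean cycle, equivalently when it
#' preserves the DCJ distance while decreasing the total indel-potential by
#' exactly one. All linearizations (rotations and both orientations) of the
#' circular singleton and all insertion sites of the target are tried by
#' rebuilding the diagram.
#'
#' @param s A singleton from [extract_singletons()].
#' @param target Genome receiving the insertion (genome A for a B-run
#'   singleton, genome B for an A-run singleton).
#' @param other The other genome.
#' @return List of sites, each with `after` (position in `target`'s stored
#'   order), `after_marker`, `tokens` (linearized signed singleton) and
#'   `result` (the genome after insertion).
#' @export
optimal_integration_sites <- function(s, target, other) {
  R0 <- build_diagram(target, other)
  c0 <- n_cycles(R0)
  sl0 <- sum_lambda(R0)
  d0 <- R0$n - c0
  toks <- s$content
  k <- length(toks)
  linearizations <- list()
  for (rot in seq_len(k)) {
    idx <- c(seq.int(rot, k), seq_len(rot - 1L))
    fwd <- toks[idx]
    linearizations[[length(linearizations) + 1L]] <- fwd
    linearizations[[length(linearizations) + 1L]] <- revflip_tokens(fwd)
  }
  # dedup identical linearizations (e.g. palindromic or length-1 content)
  keys <- vapply(linearizations, paste, character(1), collapse = " ")
  linearizations <- linearizations[!duplicated(keys)]

  sites <- list()
  for (lin in linearizations) {
    for (p in seq_len(length(target$markers))) {
      cand <- apply_operation(target, insertion_op(lin, target$markers[p]))
      R1 <- build_diagram(cand, other)
      d1 <- R1$n - n_cycles(R1)
      if (d1 == d0 && sum_lambda(R1) == sl0 - 1L) {
        stopifnot(n_cycles(R1) == c0 + length(lin))
        sites[[length(sites) + 1L]] <-
          list(after = p, after_marker = target$markers[p],
               tokens = lin, result = cand)
      }
    }
  }
  sites
}

#' Perform a safe integration of a singleton
#'
#' Among the optimal integration sites, returns one whose resulting diagram
#' has no bad component. When the input diagram has no bad component such a
#' site always exists; not finding one is surfaced as an internal invariant
#' error.
#'
#' @inheritParams optimal_integration_sites
#' @return The chosen site (as in [optimal_integration_sites()]).
#' @export
safe_integration <- function(s, target, other) {
  sites <- optimal_integration_sites(s, target, other)
  if (!length(sites))
    stop("internal invariant error: no optimal integration site found")
  for (site in sites) {
    if (!has_bad_component(site$result, other)) return(site)
  }
  stop(paste("internal invariant error: no optimal integration is safe;",
             "this contradicts the safe-integration guarantee"))
}

#' Optimal integrated completion of two genomes
#'
#' Repeatedly extracts a run and integrates its singleton into the other
#' genome (B-run singletons into A, A-run singletons into B, processing runs
#' in diagram order) until no run remains. Exactly the initial total
#' indel-potential many integrations are performed; the final diagram is all
#' clean and the DCJ distance is preserved.
#'
#' @param A,B Genomes with at least two common markers.
#' @param safe Require each integration to be safe (needs a diagram without
#'   bad components); otherwise any optimal site is used.
#' @return List with `A_star`, `B_star` and `steps`, one entry per
#'   integration (`side`, `tokens`, `after_marker`, `into`).
#' @export
integrated_completion <- function(A, B, safe = TRUE) {
  R0 <- build_diagram(A, B)
  total <- sum_lambda(R0)
  d0 <- R0$n - n_cycles(R0)
  curA <- A; curB <- B
  steps <- list()
  for (step in seq_len(total)) {
    R <- build_diagram(curA, curB)
    sl <- sum_lambda(R)
    singles <- extract_singletons(R)
    if (!length(singles)) break
    s <- singles[[1]]
    if (s$side == "B") {
      site <- if (safe) safe_integration(s, curA, curB)
              else optimal_integration_sites(s, curA, curB)[[1]]
      curA <- site$result
    } else {
      site <- if (safe) safe_integration(s, curB, curA)
              else optimal_integration_sites(s, curB, curA)[[1]]
      curB <- site$result
    }
    R1 <- build_diagram(curA, curB)
    stopifnot(sum_lambda(R1) == sl - 1L,
              R1$n - n_cycles(R1) == d0)
    steps[[length(steps) + 1L]] <-
      list(side = s$side, tokens = site$tokens,
           after_marker = site$after_marker,
           into = if (s$side == "B") "A" else "B")
  }
  Rf <- build_diagram(curA, curB)
  stopifnot(length(steps) == total,
            sum_lambda(Rf) == 0L,
            all(vapply(Rf$cycles, `[[`, integer(1), "Lambda") == 0L),
            Rf$n - n_cycles(Rf) == d0)
  list(A_star = curA, B_star = curB, steps = steps)
}

#' Sorting scenario in the absence of bad components
#'
#' Produces a shortest sequence of operations transforming `A` into `B`:
#' first one insertion per B-run singleton (safely integrated into A), then
#' split inversions sorting the completed genomes, each chosen so that the
#' diagram keeps no bad component, and finally one deletion per A-run
#' singleton. The scenario length equals the exact inversion-indel
#' distance.
#'
#' @param A,B Genomes; the relational diagram of the pair must have no bad
#'   component (checked). A single common marker is handled by the trivial
#'   delete-then-insert rule.
#' @return Object of class `inv_indel_scenario`: list with `start`, `end`,
#'   `ops` (a list of [inversion_op()]/[deletion_op()]/[insertion_op()]),
#'   and `length`.
#' @export
sort_no_bad <- function(A, B) {
  part <- classify_markers(A, B)
  ops <- list()
  if (length(part$common) == 0L)
    stop_invindel("genomes share no marker; no sorting scenario is defined",
                  "invindel_wrong_model")
  if (length(part$common) == 1L) {
    g <- part$common[1]
    cur <- A
    if (length(part$onlyB)) {
      q <- match(g, B$markers)
      Bo <- if (B$signs[q] < 0L) reflect_genome(B) else B
      Bo <- rotate_genome(Bo, match(g, Bo$markers))
      toks <- genome_tokens(Bo)[-1]
      # when A stores the common marker in reverse orientation, "after g" in
      # A's reading direction is "before g" in B's: insert the flipped block
      if (A$signs[match(g, A$markers)] < 0L) toks <- revflip_tokens(toks)
      op <- insertion_op(toks, g)
      cur <- apply_operation(cur, op)
      ops[[length(ops) + 1L]] <- op
    }
    if (length(part$onlyA)) {
      blk <- cur$markers[cur$markers %in% part$onlyA]
      cur <- apply_operation(cur, deletion_op(blk), common = part$common)
      ops[[length(ops) + 1L]] <- deletion_op(blk)
    }
    stopifnot(genomes_equal(cur, B))
    return(new_scenario(A, B, ops))
  }

  if (has_bad_component(A, B))
    stop_invindel(paste(
      "the relational diagram has a bad component; sort_no_bad() does not",
      "apply -- use inv_indel() for distance bounds"),
      "invindel_wrong_precondition")

  curA <- A; curB <- B
  deletions <- list()
  repeat {
    R <- build_diagram(curA, curB)
    singles <- extract_singletons(R)
    brun <- Filter(function(s) s$side == "B", singles)
    arun <- Filter(function(s) s$side == "A", singles)
    if (length(brun)) {
      site <- safe_integration(brun[[1]], curA, curB)
      op <- insertion_op(site$tokens, site$after_marker)
      curA <- site$result
      ops[[length(ops) + 1L]] <- op
    } else if (length(arun)) {
      site <- safe_integration(arun[[1]], curB, curA)
      curB <- site$result
      nm <- sub("^-", "", site$tokens)
      deletions[[length(deletions) + 1L]] <- nm
    } else break
  }

  # inversion phase: sort curA into curB with split inversions that keep the
  # diagram free of bad components
  repeat {
    R <- build_diagram(curA, curB)
    d <- R$n - n_cycles(R)
    if (d == 0L) break
    n <- length(curA$markers)
    found <- FALSE
    for (i in 0L:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (j - i >= n) next
        cand <- apply_operation(curA, inversion_op(i, j))
        Rc <- build_diagram(cand, curB)
        ok <- Rc$n - n_cycles(Rc) == d - 1L &&
          !any(vapply(find_components(Rc), function(k) k$class == "bad",
                      logical(1)))
        if (ok) {
          ops[[length(ops) + 1L]] <- inversion_op(i, j)
          curA <- cand
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found)
      stop(paste("internal invariant error: no safe split inversion found;",
                 "this contradicts the good-component sorting guarantee"))
  }
  stopifnot(genomes_equal(curA, curB))

  for (blk in deletions) {
    op <- deletion_op(blk)
    curA <- apply_operation(curA, op, common = part$common)
    ops[[length(ops) + 1L]] <- op
  }
  stopifnot(genomes_equal(curA, B))
  new_scenario(A, B, ops)
}

new_scenario <- function(A, B, ops) {
  kinds <- vapply(ops, `[[`, character(1), "kind")
  # insertions precede all inversions; deletions follow them
  stopifnot(!is.unsorted(match(kinds,
                               c("insertion", "inversion", "deletion"))))
  structure(list(start = A, end = B, ops = ops, length = length(ops)),
            class = "inv_indel_scenario")
}

#' Replay a sorting scenario
#'
#' Applies the scenario's operations to its start genome and checks that the
#' result equals its end genome.
#'
#' @param sc An `inv_indel_scenario`.
#' @return The final genome, invisibly; errors if the replay does not reach
#'   the scenario's end genome.
#' @export
replay_scenario <- function(sc) {
  cur <- sc$start
  common <- classify_markers(sc$start, sc$end)$common
  for (op in sc$ops) cur <- apply_operation(cur, op, common = common)
  if (!genomes_equal(cur, sc$end))
    stop_invindel("scenario replay did not reach the end genome",
                  "invindel_model_violation")
  invisible(cur)
}

#' @export
print.inv_indel_scenario <- function(x, ...) {
  cat(sprintf("Sorting scenario: %d step(s) from %s to %s\n",
              x$length, format(x$start), format(x$end)))
  for (k in seq_along(x$ops)) {
    op <- x$ops[[k]]
    desc <- switch(op$kind,
      insertion = sprintf("INS (%s) after %s",
                          paste(op$tokens, collapse = " "), op$after),
      inversion = sprintf("INV cut sites %d..%d", op$i, op$j),
      deletion = sprintf("DEL (%s)", paste(op$markers, collapse = " ")))
    cat(sprintf("  %2d. %s\n", k, desc))
  }
  invisible(x)
}
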