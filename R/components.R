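# Interleaving components of the relational diagram and the structural
# relations between them (nesting, links, chains, separation).

#' Do two cycles interleave?
#'
#' Two distinct cycles interleave when each has an orange edge whose layout
#' position lies strictly between two orange-edge positions of the other.
#'
#' @param c1,c2 Distinct cycles of one diagram.
#' @return Logical flag.
#' @export
interleaving <- function(c1, c2) {
  if (identical(c1$orange_idx, c2$orange_idx) &&
      identical(c1$id, c2$id))
    stop_invindel("interleaving is not defined for a cycle with itself",
                  "invindel_not_applicable")
  p1 <- c1$orange_idx
  p2 <- c2$orange_idx
  any(p1 > min(p2) & p1 < max(p2)) && any(p2 > min(p1) & p2 < max(p1))
}

#' Find the interleaving components of a diagram
#'
#' Components are the connected components of the interleaving graph over
#' cycles. Each is classified as `trivial` (a single 2-cycle), `bad`
#' (non-trivial with only bad cycles) or `good`, and annotated with its
#' colored dots (`"A"` if some cycle has an A-run, `"B"` likewise), whether
#' it contains a two-color cycle (two or more runs) and its maximum run
#' count.
#'
#' @param R A [build_diagram()] result.
#' @return List of components; each has `id`, `cycles` (cycle ids), `pos`
#'   (sorted orange-edge positions), `span`, `class`, `dots`, `has_AB`,
#'   `max_Lambda`.
#' @export
find_components <- function(R) {
  cys <- R$cycles
  k <- length(cys)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (cys[[i]]$n_orange >= 2L && cys[[j]]$n_orange >= 2L &&
          interleaving(cys[[i]], cys[[j]])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  comps <- list()
  for (r in unique(roots)) {
    ids <- which(roots == r)
    members <- cys[ids]
    pos <- sort(unlist(lapply(members, `[[`, "orange_idx")))
    n_orange <- vapply(members, `[[`, integer(1), "n_orange")
    cls <- if (length(ids) == 1L && n_orange[1] == 1L) {
      "trivial"
    } else {
      unsorted <- members[n_orange >= 2L]
      if (length(unsorted) &&
          all(vapply(unsorted, cycle_is_bad, logical(1)))) "bad" else "good"
    }
    run_sides <- unlist(lapply(members, function(cy)
      vapply(cy$runs, `[[`, character(1), "side")))
    Lmax <- max(vapply(members, `[[`, integer(1), "Lambda"))
    comps[[length(comps) + 1L]] <- list(
      id = NA_integer_, cycles = ids, pos = pos,
      span = c(min(pos), max(pos)), class = cls,
      dots = sort(unique(run_sides)),
      has_AB = any(vapply(members, function(cy) cy$Lambda >= 2L, logical(1))),
      max_Lambda = Lmax)
  }
  comps <- comps[order(vapply(comps, function(x) x$span[1], numeric(1)))]
  for (i in seq_along(comps)) comps[[i]]$id <- i
  comps
}

# component of the orange edge at layout position p
component_at <- function(comps, p) {
  for (k in seq_along(comps)) if (p %in% comps[[k]]$pos) return(k)
  NA_integer_
}

is_nested_in <- function(ci, cj) {
  all(ci$pos > cj$span[1] & ci$pos < cj$span[2])
}

#' Structural relations between components
#'
#' Computes the nesting partial order (by orange-span containment), linked
#' pairs with their link marker, maximal chains of linked components, and
#' separation triples (by the literal two-directional circular scan).
#'
#' @param comps Components from [find_components()].
#' @param R The diagram they came from.
#' @return List with `parent` (immediate nesting parent per component, `NA`
#'   for top level), `nested` (logical matrix, `nested[i,j]` iff component i
#'   is nested within j), `links` (data frame of linked pairs and link
#'   markers), `chains` (list of integer vectors, singleton chains
#'   included), and `separations` (data frame of triples `separator`, `c1`,
#'   `c2`).
#' @export
component_relations <- function(comps, R) {
  m <- length(comps)
  n <- R$n
  nested <- matrix(FALSE, m, m)
  if (m > 1L) {
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j) nested[i, j] <- is_nested_in(comps[[i]], comps[[j]])
    }
  }
  span_size <- vapply(comps, function(x) x$span[2] - x$span[1], numeric(1))
  parent <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    anc <- which(nested[i, ])
    if (length(anc)) parent[i] <- anc[which.min(span_size[anc])]
  }

  # linked pairs: independent, spans immediately adjacent
  links <- data.frame(c1 = integer(0), c2 = integer(0),
                      marker = character(0), stringsAsFactors = FALSE)
  if (m > 1L) {
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j || nested[i, j] || nested[j, i]) next
      if (comps[[i]]$span[2] + 1L == comps[[j]]$span[1]) {
        # layout index of the common marker between the two adjacent edges
        gidx <- comps[[i]]$span[2] + 1L
        marker <- R$lineA$order$name[gidx]
        stopifnot(identical(parent[i], parent[j]))
        links <- rbind(links, data.frame(c1 = i, c2 = j, marker = marker,
                                         stringsAsFactors = FALSE))
      }
    }
  }

  # maximal chains: group by parent, order by span, follow links
  chains <- list()
  for (p in unique(parent)) {
    grp <- if (is.na(p)) which(is.na(parent)) else which(!is.na(parent) & parent == p)
    grp <- grp[order(vapply(grp, function(i) comps[[i]]$span[1], numeric(1)))]
    cur <- grp[1]
    for (i in seq_along(grp)[-1]) {
      prev <- cur[length(cur)]
      if (comps[[prev]]$span[2] + 1L == comps[[grp[i]]]$span[1]) {
        cur <- c(cur, grp[i])
      } else {
        chains[[length(chains) + 1L]] <- cur
        cur <- grp[i]
      }
    }
    chains[[length(chains) + 1L]] <- cur
  }

  seps <- data.frame(separator = integer(0), c1 = integer(0), c2 = integer(0))
  if (m > 2L) {
    comp_of <- integer(n)
    for (k in seq_len(m)) comp_of[comps[[k]]$pos] <- k
    first_met <- function(from_comp, a, b) {
      # scan orange edges rightward (circularly) from from_comp's rightmost
      # edge; return whichever of a, b is met first
      p <- comps[[from_comp]]$span[2]
      for (step in seq_len(n - 1L)) {
        q <- (p + step - 1L) %% n + 1L
        k <- comp_of[q]
        if (k == a) return(a)
        if (k == b) return(b)
      }
      NA_integer_
    }
    for (s in seq_len(m)) for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i >= j || s == i || s == j) next
      if (first_met(i, s, j) == s && first_met(j, s, i) == s)
        seps <- rbind(seps, data.frame(separator = s, c1 = i, c2 = j))
    }
  }

  list(parent = parent, nested = nested, links = links,
       chains = chains, separations = seps)
}

#' Build a diagram whose rotation is suitable for component analysis
#'
#' The circular layout is rotated (by choice of start marker) so that, when
#' the diagram has two or more components, the first and the last orange
#' edges lie in distinct components. Start markers are tried in
#' lexicographic order; if no rotation satisfies the condition the diagram
#' has a single component and the first rotation is kept.
#'
#' @param A,B Genomes with at least two common markers.
#' @return A list with the chosen diagram `R` and its `components`.
#' @export
normalized_diagram <- function(A, B) {
  G <- classify_markers(A, B)$common
  if (length(G) < 2L)
    stop_invindel("fewer than two common markers", "invindel_trivial_case")
  fallback <- NULL
  for (s in G) {
    R <- build_diagram(A, B, start = s)
    comps <- find_components(R)
    if (length(comps) < 2L) {
      if (is.null(fallback)) fallback <- list(R = R, components = comps)
      next
    }
    if (component_at(comps, 1L) != component_at(comps, R$n))
      return(list(R = R, components = comps))
    if (is.null(fallback)) fallback <- list(R = R, components = comps)
  }
  fallback
}
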