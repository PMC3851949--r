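# Component tree T(A,B), its bad-node reduction T', the colored variants,
# cover search and the joint-inversion merge-cost table.
#
# Round nodes represent components (white = bad, black = good/trivial);
# square nodes represent maximal chains of linked components. A square node
# is the root or the child of the smallest component in which its chain is
# nested.

#' Build the component tree
#'
#' @param comps Components from [find_components()].
#' @param rel Relations from [component_relations()].
#' @return Object of class `component_tree`: a list with `nodes` (each node:
#'   `id`, `kind` round/square, `comp` for round nodes, `bad`, `dots`,
#'   `parent`, `children`) and `root`.
#' @export
build_component_tree <- function(comps, rel) {
  nodes <- list()
  add_node <- function(node) {
    node$id <- length(nodes) + 1L
    nodes[[node$id]] <<- node
    node$id
  }
  round_id <- integer(length(comps))
  for (i in seq_along(comps)) {
    round_id[i] <- add_node(list(kind = "round", comp = i,
                                 bad = comps[[i]]$class == "bad",
                                 dots = comps[[i]]$dots,
                                 parent = NA_integer_, children = integer(0)))
  }
  chain_parent <- vapply(rel$chains, function(ch) rel$parent[ch[1]],
                         integer(1))
  chain_left <- vapply(rel$chains, function(ch) comps[[ch[1]]]$span[1],
                       numeric(1))
  ord <- order(chain_left)
  root <- NA_integer_
  for (q in ord) {
    ch <- rel$chains[[q]]
    sq <- add_node(list(kind = "square", comp = NA_integer_, bad = FALSE,
                        dots = character(0), parent = NA_integer_,
                        children = round_id[ch]))
    for (i in ch) nodes[[round_id[i]]]$parent <- sq
    p <- chain_parent[q]
    if (is.na(p)) {
      if (!is.na(root))
        stop("internal invariant error: multiple top-level chains")  # nocov
      root <- sq
    } else {
      nodes[[sq]]$parent <- round_id[p]
      nodes[[round_id[p]]]$children <-
        c(nodes[[round_id[p]]]$children, sq)
    }
  }
  structure(list(nodes = nodes, root = root, comps = comps),
            class = "component_tree")
}

#' @export
print.component_tree <- function(x, ...) {
  rec <- function(id, depth) {
    nd <- x$nodes[[id]]
    lbl <- if (nd$kind == "square") "[chain]" else {
      dots <- if (length(nd$dots))
        paste0(" dots={",
               paste(ifelse(nd$dots == "A", "orange", "blue"), collapse = ","),
               "}") else ""
      sprintf("component %d (%s)%s", nd$comp,
              if (nd$bad) "bad" else "good", dots)
    }
    cat(strrep("  ", depth), lbl, "\n", sep = "")
    for (ch in nd$children) rec(ch, depth + 1L)
  }
  rec(x$root, 0L)
  invisible(x)
}

#' Reduce the component tree to its bad-node subtree
#'
#' Returns the smallest subgraph of the unrooted view of the tree containing
#' all bad nodes, together with its leaves, per-leaf long-branch flags and,
#' for the colored variant, per-leaf dot unions (over the leaf's original
#' rooted subtree).
#'
#' @param tree A [build_component_tree()] result.
#' @param colored Compute per-leaf dot unions for the colored cover.
#' @param reclass Optional integer vector of component indices whose bad
#'   classification is suppressed (used by the indel-aware normalization).
#' @return Object of class `reduced_tree` with `nodes` (ids into the
#'   original tree), `adj` (adjacency list), `bad`, `leaves`, `w`,
#'   `long_branch` (named by leaf id), `leaf_dots`, `node_dots`.
#' @export
reduce_component_tree <- function(tree, colored = FALSE, reclass = integer(0)) {
  nn <- length(tree$nodes)
  bad <- vapply(tree$nodes, function(nd)
    isTRUE(nd$bad) && !(nd$comp %in% reclass), logical(1))
  adj <- vector("list", nn)
  for (id in seq_len(nn)) {
    nd <- tree$nodes[[id]]
    nb <- c(nd$parent, nd$children)
    adj[[id]] <- nb[!is.na(nb)]
  }
  keep <- rep(TRUE, nn)
  deg <- lengths(adj)
  # iteratively prune non-terminal leaves of the unrooted tree
  repeat {
    prune <- which(keep & deg <= 1L & !bad)
    if (!length(prune)) break
    for (id in prune) {
      keep[id] <- FALSE
      for (nb in adj[[id]]) if (keep[nb]) deg[nb] <- deg[nb] - 1L
      deg[id] <- 0L
    }
  }
  if (!any(keep & bad)) {
    return(structure(list(tree = tree, nodes = integer(0),
                          adj = list(), bad = integer(0), leaves = integer(0),
                          w = 0L, long_branch = logical(0),
                          leaf_dots = list(), node_dots = list(),
                          colored = colored),
                     class = "reduced_tree"))
  }
  nodes <- which(keep)
  radj <- lapply(seq_len(nn), function(id)
    if (keep[id]) adj[[id]][keep[adj[[id]]]] else integer(0))
  rdeg <- lengths(radj)
  leaves <- nodes[rdeg[nodes] <= 1L]
  stopifnot(all(bad[leaves]))   # leaves of the reduction are bad nodes
  w <- length(leaves)

  # long-branch flag: path from leaf to the nearest node of reduced degree
  # >= 3 (exclusive), or the whole reduction if it is a path, contains >= 2
  # bad nodes
  long_branch <- logical(w)
  names(long_branch) <- as.character(leaves)
  has_branching <- any(rdeg[nodes] >= 3L)
  for (k in seq_along(leaves)) {
    if (!has_branching) {
      long_branch[k] <- sum(bad[nodes]) >= 2L
      next
    }
    cur <- leaves[k]; prev <- 0L; nbad <- 0L
    repeat {
      if (rdeg[cur] >= 3L) break
      if (bad[cur]) nbad <- nbad + 1L
      nxt <- setdiff(radj[[cur]], prev)
      if (!length(nxt)) break
      prev <- cur; cur <- nxt[1]
    }
    long_branch[k] <- nbad >= 2L
  }

  node_dots <- lapply(seq_len(nn), function(id) tree$nodes[[id]]$dots)
  leaf_dots <- list()
  if (colored) {
    subtree_dots <- function(id) {
      nd <- tree$nodes[[id]]
      dots <- nd$dots
      for (ch in nd$children) dots <- union(dots, subtree_dots(ch))
      sort(dots)
    }
    leaf_dots <- lapply(leaves, subtree_dots)
    names(leaf_dots) <- as.character(leaves)
    for (k in seq_along(leaves))
      node_dots[[leaves[k]]] <- leaf_dots[[k]]
  }

  structure(list(tree = tree, nodes = nodes, adj = radj,
                 bad = which(bad & keep), leaves = leaves, w = w,
                 long_branch = long_branch, leaf_dots = leaf_dots,
                 node_dots = node_dots, colored = colored),
            class = "reduced_tree")
}

#' @export
print.reduced_tree <- function(x, ...) {
  cat(sprintf("Reduced component tree: %d node(s), %d bad, w = %d leaf/leaves\n",
              length(x$nodes), length(x$bad), x$w))
  if (x$w) cat("  long-branch leaves:", sum(x$long_branch), "\n")
  invisible(x)
}

#' Extra inversion cost for bad components
#'
#' The closed form on the plain reduced tree: with `w` leaves, the
#' cost is `w + 1` if `w` is odd and every leaf lies on a long branch, and
#' `w` otherwise (0 when there is no bad component).
#'
#' @param red A plain (uncolored) [reduce_component_tree()] result.
#' @return Integer \eqn{\tau_{INV}}.
#' @export
tau_inv <- function(red) {
  w <- red$w
  if (w == 0L) return(0L)
  if (w %% 2L == 1L && all(red$long_branch)) w + 1L else w
}

# ---- exhaustive cover search -------------------------------------------

# pairwise paths between nodes of the reduced tree
reduced_paths <- function(red) {
  nodes <- red$nodes
  paths <- list()
  for (s in nodes) {
    prev <- integer(max(nodes))
    seen <- rep(FALSE, max(nodes))
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (nb in red$adj[[v]]) if (!seen[nb]) {
        seen[nb] <- TRUE; prev[nb] <- v; queue <- c(queue, nb)
      }
    }
    for (t in nodes) {
      p <- t
      path <- t
      while (p != s) { p <- prev[p]; path <- c(path, p) }
      paths[[paste(s, t)]] <- path
    }
  }
  paths
}

# minimum cost of covering bad-node block `blk` with one path
block_path_cost <- function(red, blk, paths, colored) {
  if (length(blk) == 1L) return(list(cost = 1L, ends = c(blk, blk)))
  # the block must lie on a single path; find extremal endpoints among blk
  base <- NULL
  for (i in seq_along(blk)) for (j in seq_along(blk)) {
    if (i >= j) next
    p <- paths[[paste(blk[i], blk[j])]]
    if (all(blk %in% p)) { base <- c(blk[i], blk[j]); break }
  }
  if (is.null(base)) return(NULL)   # not coverable by one path
  if (!colored) return(list(cost = 2L, ends = base))
  # colored: a long path costs 1 if its endpoints share a colored dot; the
  # path may be extended beyond the extremal bad nodes to reach such a pair
  for (x in red$nodes) for (y in red$nodes) {
    dx <- red$node_dots[[x]]; dy <- red$node_dots[[y]]
    if (!length(intersect(dx, dy))) next
    p <- paths[[paste(x, y)]]
    if (all(blk %in% p)) return(list(cost = 1L, ends = c(x, y)))
  }
  list(cost = 2L, ends = base)
}

# exhaustive minimum-cost cover over partitions of the bad nodes into paths
cover_search <- function(red, colored) {
  bad <- red$bad
  if (!length(bad)) return(list(cost = 0L, paths = list()))
  paths <- reduced_paths(red)
  blocks_cost <- new.env(parent = emptyenv())
  cost_of <- function(blk) {
    key <- paste(blk, collapse = ",")
    if (!is.null(blocks_cost[[key]])) return(blocks_cost[[key]])
    res <- block_path_cost(red, blk, paths, colored)
    blocks_cost[[key]] <- if (is.null(res)) list(cost = Inf, ends = NULL) else res
    blocks_cost[[key]]
  }
  best <- list(cost = Inf, paths = list())
  recurse <- function(rest, blocks, acc) {
    if (acc >= best$cost) return()
    if (!length(rest)) {
      paths_out <- lapply(blocks, function(blk) cost_of(blk)$ends)
      best <<- list(cost = acc, paths = paths_out, blocks = blocks)
      return()
    }
    v <- rest[1]; rest2 <- rest[-1]
    # add v to an existing block
    for (bi in seq_along(blocks)) {
      blk2 <- sort(c(blocks[[bi]], v))
      c2 <- cost_of(blk2)$cost
      if (is.finite(c2)) {
        old <- cost_of(blocks[[bi]])$cost
        nb <- blocks; nb[[bi]] <- blk2
        recurse(rest2, nb, acc - old + c2)
      }
    }
    # open a new block with v
    recurse(rest2, c(blocks, list(v)), acc + 1L)
  }
  recurse(bad[-1], list(bad[1]), 1L)
  best
}

#' Optimal colored cover of the reduced colored tree
#'
#' Exhaustive search over path covers of the bad nodes, with short paths
#' costing 1 and long paths costing 2, or 1 when their endpoints share a
#' colored dot. The cost of the optimal colored cover corresponds to the
#' extra inversion-indel cost of the bad components (asserted, not proven,
#' to be exact).
#'
#' @param red A colored [reduce_component_tree()] result.
#' @param cap Maximum number of reduced-tree nodes the exhaustive search
#'   accepts (default 16).
#' @return List with `cost` and `paths` (endpoint pairs of the cover paths).
#' @export
optimal_colored_cover <- function(red, cap = 16L) {
  if (!red$colored && red$w > 0L)
    stop_invindel("optimal_colored_cover expects a colored reduction",
                  "invindel_format")
  if (length(red$nodes) > cap)
    stop_invindel(sprintf(
      "reduced tree has %d nodes (> cap %d); use tau_indel_bounds()",
      length(red$nodes), cap), "invindel_too_large")
  cover_search(red, colored = TRUE)
}

# plain-cost cover search (validation oracle for tau_inv)
optimal_plain_cover <- function(red, cap = 16L) {
  if (length(red$nodes) > cap)
    stop_invindel("reduced tree too large for exhaustive cover search",
                  "invindel_too_large")
  cover_search(red, colored = FALSE)
}

#' Bounds on the extra inversion-indel cost of bad components
#'
#' With `w` the number of leaves of the reduced colored tree, the optimal
#' cover cost lies between `ceiling(w/2)` and `w + 1` (and is 0 when there
#' is no bad component).
#'
#' @param red A [reduce_component_tree()] result.
#' @return Integer vector `c(lower, upper)`.
#' @export
tau_indel_bounds <- function(red) {
  w <- red$w
  if (w == 0L) return(c(lower = 0L, upper = 0L))
  c(lower = as.integer(ceiling(w / 2)), upper = w + 1L)
}

#' Cost of a joint inversion merging two cycles
#'
#' Cycle run-types: `"Ce"` (no run), `"CA"`/`"CB"` (a single A-/B-run),
#' `"CAB"` (two or more runs), `"Cstar"` (any). Returns the change in total
#' indel-potential and the net cost `delta_d = 2 + delta_lambda` of the
#' merge.
#'
#' @param type1,type2 Run-types of the two cycles.
#' @return List with `delta_lambda` and `delta_d`.
#' @export
merge_cost <- function(type1, type2) {
  types <- c("Ce", "CA", "CB", "CAB", "Cstar")
  if (!(type1 %in% types) || !(type2 %in% types))
    stop_invindel("unknown cycle run-type", "invindel_format")
  pair <- sort(c(type1, type2))
  key <- paste(pair, collapse = "+")
  dl <- switch(key,
    "CAB+CAB" = -2L,
    "CA+CA" = -1L,
    "CB+CB" = -1L,
    "CA+CAB" = -1L,
    "CAB+CB" = -1L,
    "CA+CB" = 0L,
    {
      if ("Ce" %in% pair) 0L
      else stop_invindel(sprintf("merge type %s not in the cost table", key),
                         "invindel_format")
    })
  list(delta_lambda = dl, delta_d = 2L + dl)
}

# run-type of a cycle
cycle_run_type <- function(cy) {
  if (cy$Lambda == 0L) "Ce"
  else if (cy$Lambda >= 2L) "CAB"
  else if (cy$runs[[1]]$side == "A") "CA" else "CB"
}

#' Reclassify bad components that indels make free to resolve
#'
#' For the indel-aware cover two standing assumptions are encoded as
#' reclassifications: (a) a bad component containing a cycle with four or
#' more runs can be cut at no net cost, so it counts as good; (b) when two
#' or more components contain a two-color cycle, they (and every component
#' separating a pair of them) can be merged into one good component at no
#' net cost, so the bad ones among them count as good.
#'
#' @param comps Components.
#' @param rel Relations (for separation triples).
#' @return Integer vector of component indices to treat as good.
#' @export
reclassified_good <- function(comps, rel) {
  out <- integer(0)
  bad_ids <- which(vapply(comps, function(k) k$class == "bad", logical(1)))
  for (i in bad_ids)
    if (comps[[i]]$max_Lambda >= 4L) out <- c(out, i)
  ab_ids <- which(vapply(comps, function(k) isTRUE(k$has_AB), logical(1)))
  if (length(ab_ids) >= 2L) {
    out <- c(out, intersect(bad_ids, ab_ids))
    if (nrow(rel$separations)) {
      for (r in seq_len(nrow(rel$separations))) {
        s <- rel$separations$separator[r]
        if (s %in% bad_ids &&
            rel$separations$c1[r] %in% ab_ids &&
            rel$separations$c2[r] %in% ab_ids)
          out <- c(out, s)
      }
    }
  }
  sort(unique(out))
}
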