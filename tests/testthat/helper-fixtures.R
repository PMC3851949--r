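# Worked-example genomes (single circular chromosome each) and small
# constructors shared across the test files.

fig2_A <- function() parse_genome("(a w -d -c y b -z -e f x i j h g)")
fig2_B <- function() parse_genome("(a s b c d u v e f g h i t j r)")
fig4_A <- function() parse_genome("(a x -c y b -z -d)")
fig4_B <- function() parse_genome("(a u b c v d)")
fig5_A <- function() parse_genome("(a -c b e d)")
fig5_B <- function() parse_genome("(a b x c y d z e)")

# unsigned (all-direct) random permutation against the identity: a rich
# source of diagrams with bad components
random_unsigned_pair <- function(n) {
  perm <- c(1L, 1L + sample(n - 1L))
  list(A = genome(paste0("g", perm), label = "A"),
       B = genome(paste0("g", seq_len(n)), label = "B"))
}

has_bad <- function(A, B) {
  comps <- find_components(build_diagram(A, B))
  any(vapply(comps, function(k) k$class == "bad", logical(1)))
}

component_classes <- function(A, B) {
  nd <- normalized_diagram(A, B)
  sort(vapply(nd$components, `[[`, character(1), "class"))
}

# hand-built reduced trees for the cover search (kept minimal: only the
# fields the cover machinery reads)
make_reduced <- function(edges, bad, dots = NULL, colored = TRUE) {
  nn <- max(unlist(edges), if (length(bad)) bad else 1L)
  adj <- vector("list", nn)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  nodes <- sort(unique(c(unlist(edges), bad)))
  deg <- lengths(adj)
  leaves <- nodes[deg[nodes] <= 1L]
  node_dots <- rep(list(character(0)), nn)
  if (!is.null(dots)) for (nm in names(dots)) {
    node_dots[[as.integer(nm)]] <- dots[[nm]]
  }
  structure(list(tree = NULL, nodes = nodes, adj = adj, bad = bad,
                 leaves = leaves, w = length(leaves),
                 long_branch = stats::setNames(rep(FALSE, length(leaves)),
                                               leaves),
                 leaf_dots = node_dots[leaves], node_dots = node_dots,
                 colored = colored),
            class = "reduced_tree")
}
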