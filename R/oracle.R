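# Brute-force breadth-first-search reference implementations, used as
# ground truth on tiny instances. States are deduplicated by the canonical
# form of the circular genome (rotation- and reflection-invariant), encoded
# as an exact integer key so hashing stays cheap.

# --- fast canonical keys -------------------------------------------------

# Map a genome onto signed integers over a fixed marker universe.
encode_genome <- function(g, universe) {
  ids <- match(g$markers, universe)
  stopifnot(!anyNA(ids))
  ids * g$signs
}

decode_genome <- function(v, universe) {
  genome(ifelse(v < 0L, paste0("-", universe[-v]), universe[v]))
}

# Canonical numeric key: minimum over all rotations of v and of its
# reflection of the base-(2m+1) encoding. Exact for length(v)*log2(2m+1)
# below 53 bits, which the oracle size limits guarantee.
canonical_key <- function(v, m) {
  n <- length(v)
  f <- function(x) 2L * abs(x) - (x > 0L)   # 1..2m, injective on +-1..m
  base <- 2 * m + 1
  pows <- base^(seq_len(n) - 1)
  best <- Inf
  w <- -rev(v)
  for (k in seq_len(n)) {
    idx <- c(seq.int(k, n), seq_len(k - 1L))
    best <- min(best, sum(f(v[idx]) * pows), sum(f(w[idx]) * pows))
  }
  best
}

invert_segment <- function(v, i, j) {
  v[i:j] <- -rev(v[i:j])
  v
}

#' Exact inversion distance by breadth-first search
#'
#' Explores all inversions from `A` until `B`'s canonical form is reached.
#' Only suitable for tiny instances (about six markers).
#'
#' @param A,B Genomes over the same marker set.
#' @param max_depth Search cap; reaching it raises a search-exhausted error.
#' @return Integer distance.
#' @export
bfs_inversion_distance <- function(A, B, max_depth = NULL) {
  if (!setequal(A$markers, B$markers))
    stop_invindel("equal marker content required", "invindel_wrong_model")
  n <- length(A$markers)
  universe <- sort(A$markers)
  m <- length(universe)
  if (is.null(max_depth)) max_depth <- n + 1L
  v0 <- encode_genome(A, universe)
  target <- canonical_key(encode_genome(B, universe), m)
  if (canonical_key(v0, m) == target) return(0L)
  seen <- new.env(parent = emptyenv())
  seen[[as.character(canonical_key(v0, m))]] <- TRUE
  frontier <- list(v0)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (v in frontier) {
      for (i in seq_len(n)) for (j in i:n) {
        if (j - i + 1L >= n) next
        v2 <- invert_segment(v, i, j)
        key <- as.character(canonical_key(v2, m))
        if (key == as.character(target)) return(depth)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nxt[[length(nxt) + 1L]] <- v2
        }
      }
    }
    if (!length(nxt))
      stop_invindel("target not reachable by inversions", "invindel_exhausted")
    frontier <- nxt
  }
  stop_invindel("BFS depth cap reached before target", "invindel_exhausted")
}

#' Exact inversion-indel distance by breadth-first search
#'
#' Moves are: any inversion; any deletion of a contiguous block containing
#' no marker of `B`; any insertion, at any site, of any signed arrangement
#' of any nonempty subset of `B`'s unique markers not currently present.
#' Every move is invertible with the roles of the two genomes swapped, so
#' the search runs bidirectionally (level-synchronous from both ends),
#' which keeps the explored state space small. Only suitable for very small
#' instances (about four common markers and two unique markers per genome).
#'
#' @param A,B Genomes (unequal content allowed).
#' @param max_depth Search cap; defaults to a crude independent upper bound
#'   `|A| + |B| + 2`.
#' @return Integer distance.
#' @export
bfs_inversion_indel_distance <- function(A, B, max_depth = NULL) {
  universe <- sort(union(A$markers, B$markers))
  m <- length(universe)
  if (is.null(max_depth)) max_depth <- length(A) + length(B) + 2L
  vA <- encode_genome(A, universe)
  vB <- encode_genome(B, universe)
  keyA <- as.character(canonical_key(vA, m))
  keyB <- as.character(canonical_key(vB, m))
  if (keyA == keyB) return(0L)

  # precompute insertable arrangements per subset of a side's unique ids
  arrangements <- function(ids) {
    if (!length(ids)) return(list())
    subsets <- unlist(lapply(seq_along(ids), function(k)
      utils::combn(ids, k, simplify = FALSE)), recursive = FALSE)
    out <- list()
    for (sub in subsets) {
      for (perm in permutations_of(sub)) {
        k <- length(perm)
        for (smask in 0:(2^k - 1)) {
          signs <- ifelse(bitwAnd(smask, 2^(seq_len(k) - 1L)) > 0L, -1L, 1L)
          out[[length(out) + 1L]] <- perm * signs
        }
      }
    }
    out
  }
  only_B <- which(universe %in% B$markers & !(universe %in% A$markers))
  only_A <- which(universe %in% A$markers & !(universe %in% B$markers))

  neighbors <- function(v, deletable, ins_blocks) {
    n <- length(v)
    out <- list()
    for (i in seq_len(n)) for (j in i:n) {        # inversions
      if (j - i + 1L >= n) next
      out[[length(out) + 1L]] <- invert_segment(v, i, j)
    }
    if (length(deletable)) {                       # deletions (may wrap)
      del_ok <- abs(v) %in% deletable
      if (any(del_ok)) {
        for (s in seq_len(n)) for (len in seq_len(n - 1L)) {
          blk <- (s - 1L + seq_len(len) - 1L) %% n + 1L
          if (!all(del_ok[blk])) next
          out[[length(out) + 1L]] <- v[-blk]
        }
      }
    }
    if (length(ins_blocks)) {                      # insertions
      present <- abs(v)
      for (blk in ins_blocks) {
        if (any(abs(blk) %in% present)) next
        for (p in 0:(n - 1L)) {
          out[[length(out) + 1L]] <- append(v, blk, after = p)
        }
      }
    }
    out
  }

  sides <- list(
    fwd = list(frontier = list(vA), depth = 0L,
               deletable = which(!(universe %in% B$markers)),
               ins_blocks = arrangements(only_B),
               seen = new.env(parent = emptyenv())),
    rev = list(frontier = list(vB), depth = 0L,
               deletable = which(!(universe %in% A$markers)),
               ins_blocks = arrangements(only_A),
               seen = new.env(parent = emptyenv())))
  assign(keyA, 0L, envir = sides$fwd$seen)
  assign(keyB, 0L, envir = sides$rev$seen)

  best <- Inf
  repeat {
    dsum <- sides$fwd$depth + sides$rev$depth
    if (best <= dsum + 1L) return(as.integer(best))
    if (dsum >= max_depth)
      stop_invindel("BFS depth cap reached before target", "invindel_exhausted")
    g <- if (length(sides$fwd$frontier) <= length(sides$rev$frontier))
      "fwd" else "rev"
    o <- setdiff(c("fwd", "rev"), g)
    side <- sides[[g]]
    other_seen <- sides[[o]]$seen
    d1 <- side$depth + 1L
    nxt <- list()
    for (v in side$frontier) {
      for (v2 in neighbors(v, side$deletable, side$ins_blocks)) {
        key <- as.character(canonical_key(v2, m))
        hit <- other_seen[[key]]
        if (!is.null(hit)) best <- min(best, d1 + hit)
        if (is.null(side$seen[[key]])) {
          assign(key, d1, envir = side$seen)
          nxt[[length(nxt) + 1L]] <- v2
        }
      }
    }
    if (!length(nxt) && !is.finite(best))
      stop_invindel("target not reachable", "invindel_exhausted")
    sides[[g]]$frontier <- nxt
    sides[[g]]$depth <- d1
  }
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    for (rest in permutations_of(x[-k]))
      out[[length(out) + 1L]] <- c(x[k], rest)
  }
  out
}

#' Exact DCJ distance by breadth-first search
#'
#' States are multichromosomal sets of circular chromosomes (a DCJ may
#' excise and reintegrate circular intermediates); moves are both
#' rejoinings of every pair of adjacencies.
#'
#' @param A,B Genomes over the same marker set (about five markers at most).
#' @param max_depth Search cap.
#' @return Integer distance.
#' @export
bfs_dcj_distance <- function(A, B, max_depth = NULL) {
  if (!setequal(A$markers, B$markers))
    stop_invindel("equal marker content required", "invindel_wrong_model")
  universe <- sort(A$markers)
  m <- length(universe)
  n <- length(A$markers)
  if (is.null(max_depth)) max_depth <- n + 1L

  state_key <- function(chroms) {
    paste(sort(vapply(chroms, canonical_key, numeric(1), m = m)),
          collapse = "|")
  }
  rotate_at <- function(v, s) {
    # linearize the circle starting right after cut site s (after position s)
    k <- length(v)
    if (s == k) v else c(v[(s + 1L):k], v[seq_len(s)])
  }
  dcj_moves <- function(chroms) {
    out <- list()
    nc <- length(chroms)
    cuts <- do.call(rbind, lapply(seq_len(nc), function(ci)
      cbind(ci, seq_along(chroms[[ci]]))))
    np <- nrow(cuts)
    for (a in seq_len(np - 1L)) for (b in (a + 1L):np) {
      c1 <- cuts[a, 1]; s1 <- cuts[a, 2]
      c2 <- cuts[b, 1]; s2 <- cuts[b, 2]
      if (c1 == c2) {
        v <- chroms[[c1]]
        lo <- min(s1, s2); hi <- max(s1, s2)
        seg <- (lo + 1L):hi
        inv <- v; inv[seg] <- -rev(inv[seg])
        out[[length(out) + 1L]] <- c(chroms[-c1], list(inv))
        out[[length(out) + 1L]] <- c(chroms[-c1],
                                     list(v[seg], v[-seg]))
      } else {
        l1 <- rotate_at(chroms[[c1]], s1)
        l2 <- rotate_at(chroms[[c2]], s2)
        out[[length(out) + 1L]] <- c(chroms[-c(c1, c2)], list(c(l1, l2)))
        out[[length(out) + 1L]] <- c(chroms[-c(c1, c2)],
                                     list(c(l1, -rev(l2))))
      }
    }
    out
  }

  start <- list(encode_genome(A, universe))
  target <- state_key(list(encode_genome(B, universe)))
  if (state_key(start) == target) return(0L)
  seen <- new.env(parent = emptyenv())
  seen[[state_key(start)]] <- TRUE
  frontier <- list(start)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (st in frontier) {
      for (st2 in dcj_moves(st)) {
        key <- state_key(st2)
        if (key == target) return(depth)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nxt[[length(nxt) + 1L]] <- st2
        }
      }
    }
    if (!length(nxt))
      stop_invindel("target not reachable", "invindel_exhausted")
    frontier <- nxt
  }
  stop_invindel("BFS depth cap reached before target", "invindel_exhausted")
}

# --- split-DCJ minimization oracle for the indel-potential ---------------

#' Minimum run count achievable by split-DCJ sorting of one cycle
#'
#' Exhaustively sorts an abstract cycle (alternating colored edges with
#' label sizes) down to 2-cycles using split DCJ operations only, and
#' returns the minimum total number of runs of the resulting 2-cycles. This
#' is the quantity the indel-potential formula predicts from the initial run
#' count alone.
#'
#' @param sizes Integer vector of label sizes of the cycle's colored edges
#'   in traversal order; colors alternate, odd positions belonging to genome
#'   A. Length must be even.
#' @return Integer minimum number of runs (= indels) after sorting.
#' @export
min_runs_split_dcj <- function(sizes) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) %% 2L == 0L, all(sizes >= 0L))
  memo <- new.env(parent = emptyenv())
  split_dcj_solve(sizes, memo)
}

cycle_canon <- function(sizes) {
  k <- length(sizes)
  best <- NULL
  seqs <- list(sizes, rev(sizes))
  for (s in seqs) {
    for (r in seq.int(1L, k, by = 2L)) {   # even rotations keep colors fixed
      idx <- c(seq.int(r, k), seq_len(r - 1L))
      cand <- paste(s[idx], collapse = ",")
      if (is.null(best) || cand < best) best <- cand
    }
  }
  best
}

cycle_runs_count <- function(sizes) {
  lab <- which(sizes > 0L)
  if (!length(lab)) return(0L)
  cols <- lab %% 2L
  grp <- cumsum(c(TRUE, cols[-1] != cols[-length(cols)]))
  ngrp <- max(grp)
  if (ngrp > 1L && cols[1] == cols[length(cols)]) ngrp <- ngrp - 1L
  as.integer(ngrp)
}

split_dcj_solve <- function(sizes, memo) {
  k <- length(sizes)
  if (k == 2L) return(sum(sizes > 0L))
  key <- cycle_canon(sizes)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  best <- Inf
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j || (j - i) %% 2L != 0L) next      # same color only
    for (p in 0:sizes[i]) for (q in 0:sizes[j]) {
      # cut edge i after p labels and edge j after q labels; the split
      # rejoining closes the two arcs, fusing the loose half-edges
      arc1 <- if (i + 1L <= j - 1L) sizes[(i + 1L):(j - 1L)] else integer(0)
      arc2 <- if (j + 1L <= k) sizes[seq.int(j + 1L, k)] else integer(0)
      if (i - 1L >= 1L) arc2 <- c(arc2, sizes[seq_len(i - 1L)])
      c1 <- c(q + (sizes[i] - p), arc1)
      c2 <- c(p + (sizes[j] - q), arc2)
      val <- split_dcj_solve(c1, memo) + split_dcj_solve(c2, memo)
      if (val < best) best <- val
    }
  }
  memo[[key]] <- as.integer(best)
  as.integer(best)
}
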