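# The relational diagram R(A,B).
#
# Both genomes are drawn on a horizontal line of 2|G| vertices, one per
# extremity (tail g^t / head g^h) of each common marker. A chosen start
# marker is rotated into direct orientation at the front of each genome, so
# the leftmost vertex of each line is a^h and the rightmost a^t. Orange edges
# (genome A) and blue edges (genome B) join layout positions (2i-1, 2i) and
# carry the unique markers lying between the two extremities as their label;
# dotted edges match equal extremities across the lines. Every vertex has
# degree two, so the diagram decomposes into cycles whose length is a
# multiple of four.

#' Build the relational diagram of two genomes
#'
#' @param A,B Genomes sharing at least two markers.
#' @param start Start marker used to linearize the circular layout; defaults
#'   to the lexicographically smallest common marker.
#' @return An object of class `relational_diagram` with components `n`
#'   (number of common markers), `start`, `edgesA`/`edgesB` (per-line edge
#'   tables), and `cycles` (see Details).
#'
#' @details Each cycle is traversed starting from its leftmost upper-line
#'   vertex, first moving along that vertex's orange edge; this fixes a
#'   direction for every colored edge. A cycle records its colored edges in
#'   traversal order (`line`, `idx`, `dir`; `dir = 1` means left-to-right in
#'   the layout), the edge labels read in traversal direction, its runs, the
#'   run count `Lambda` and the indel-potential `lambda`.
#' @export
build_diagram <- function(A, B, start = NULL) {
  part <- classify_markers(A, B)
  G <- part$common
  if (length(G) < 2L)
    stop_invindel(paste0(
      "fewer than two common markers: the distance problem is trivial, ",
      "see inversion_indel_distance()"), "invindel_trivial_case")
  if (is.null(start)) start <- G[1]
  if (!(start %in% G))
    stop_invindel("start marker is not a common marker", "invindel_format")

  lineA <- genome_line(A, G, start)
  lineB <- genome_line(B, G, start)
  n <- length(G)

  # dotted matching: extremity string -> position on each line
  posA <- match_ext(lineA$verts)
  posB <- match_ext(lineB$verts)

  cycles <- walk_cycles(lineA, lineB, posA, posB, n)
  cycles <- lapply(seq_along(cycles), function(i) {
    cy <- annotate_cycle(cycles[[i]], lineA, lineB)
    cy$id <- i
    cy
  })

  stopifnot(sum(vapply(cycles, function(cy) cy$n_orange, integer(1))) == n)

  structure(list(n = n, start = start, common = G,
                 A = A, B = B,
                 lineA = lineA, lineB = lineB,
                 edgesA = lineA$edges, edgesB = lineB$edges,
                 cycles = cycles),
            class = "relational_diagram")
}

# Rotate/reflect genome so `start` is first and direct; extract the common-
# marker order, the vertex layout and the colored edges of its line.
genome_line <- function(g, G, start) {
  p <- match(start, g$markers)
  if (g$signs[p] < 0L) {
    g <- reflect_genome(g)
    p <- match(start, g$markers)
  }
  g <- rotate_genome(g, p)
  is_common <- g$markers %in% G
  cpos <- which(is_common)
  cname <- g$markers[cpos]
  csign <- g$signs[cpos]
  m <- length(cpos)
  # unique-marker labels between consecutive common markers (block i sits
  # between common marker i and i+1; block m wraps to the front, but the
  # rotation puts `start` first so the wrap block is just the tail)
  labels <- vector("list", m)
  ntot <- length(g$markers)
  for (i in seq_len(m)) {
    from <- cpos[i] + 1L
    to <- if (i < m) cpos[i + 1L] - 1L else ntot
    labels[[i]] <- if (from <= to) {
      idx <- from:to
      ifelse(g$signs[idx] < 0L, paste0("-", g$markers[idx]), g$markers[idx])
    } else character(0)
  }
  # vertex layout: a^h, then (tail,head) or (head,tail) per marker, then a^t
  verts <- character(2L * m)
  verts[1] <- paste0(cname[1], ".h")
  for (i in seq_len(m)[-1]) {
    ends <- if (csign[i] > 0L) c(".t", ".h") else c(".h", ".t")
    verts[2L * i - 2L] <- paste0(cname[i], ends[1])
    verts[2L * i - 1L] <- paste0(cname[i], ends[2])
  }
  verts[2L * m] <- paste0(cname[1], ".t")
  edges <- data.frame(idx = seq_len(m),
                      left = verts[2L * seq_len(m) - 1L],
                      right = verts[2L * seq_len(m)],
                      stringsAsFactors = FALSE)
  edges$label <- labels
  list(genome = g, order = data.frame(name = cname, sign = csign,
                                      stringsAsFactors = FALSE),
       verts = verts, edges = edges)
}

match_ext <- function(verts) {
  stats::setNames(seq_along(verts), verts)
}

# Walk the degree-2 graph. Colored edge at upper position p is orange edge
# ceiling(p/2); dotted edges connect equal extremities across lines.
walk_cycles <- function(lineA, lineB, posA, posB, n) {
  visitedA <- rep(FALSE, 2L * n)
  cycles <- list()
  repeat {
    startv <- which(!visitedA)[1]
    if (is.na(startv)) break
    walk <- list()
    line <- "A"; pos <- startv
    repeat {
      # colored step
      eidx <- as.integer(ceiling(pos / 2))
      at_left <- (pos %% 2L) == 1L
      dir <- if (at_left) 1L else -1L
      walk[[length(walk) + 1L]] <- list(line = line, idx = eidx, dir = dir)
      if (line == "A") {
        visitedA[pos] <- TRUE
        pos2 <- if (at_left) pos + 1L else pos - 1L
        visitedA[pos2] <- TRUE
        ext <- lineA$verts[pos2]
        line <- "B"; pos <- posB[[ext]]
      } else {
        pos2 <- if (at_left) pos + 1L else pos - 1L
        ext <- lineB$verts[pos2]
        line <- "A"; pos <- posA[[ext]]
      }
      if (line == "A" && pos == startv) break
    }
    cycles[[length(cycles) + 1L]] <- walk
  }
  cycles
}

annotate_cycle <- function(walk, lineA, lineB) {
  m <- length(walk)
  line <- vapply(walk, `[[`, character(1), "line")
  idx <- vapply(walk, `[[`, integer(1), "idx")
  dir <- vapply(walk, `[[`, integer(1), "dir")
  labels <- vector("list", m)
  for (k in seq_len(m)) {
    lab <- if (line[k] == "A") lineA$edges$label[[idx[k]]]
           else lineB$edges$label[[idx[k]]]
    if (dir[k] < 0L) lab <- revflip_tokens(lab)
    labels[[k]] <- lab
  }
  edges <- data.frame(line = line, idx = idx, dir = dir,
                      stringsAsFactors = FALSE)
  runs <- cycle_runs(line, labels)
  cy <- list(edges = edges, labels = labels,
             n_orange = sum(line == "A"),
             orange_idx = sort(idx[line == "A"]),
             orange_dir = dir[line == "A"],
             runs = runs, Lambda = length(runs))
  cy$lambda <- indel_potential_value(cy$Lambda)
  stopifnot(cy$Lambda == 0L || cy$Lambda == 1L || cy$Lambda %% 2L == 0L)
  cy
}

revflip_tokens <- function(toks) {
  if (!length(toks)) return(toks)
  rev(ifelse(startsWith(toks, "-"), sub("^-", "", toks), paste0("-", toks)))
}

# Runs: maximal cyclic blocks of labeled edges of one color (clean edges may
# sit inside a run; a block spanning the walk's start/end counts once).
cycle_runs <- function(line, labels) {
  lab_idx <- which(lengths(labels) > 0L)
  if (!length(lab_idx)) return(list())
  cols <- line[lab_idx]
  grp <- cumsum(c(TRUE, cols[-1] != cols[-length(cols)]))
  ngrp <- max(grp)
  if (ngrp > 1L && cols[1] == cols[length(cols)]) {
    # cyclic wrap: the last color block continues into the first one
    merged <- c(lab_idx[grp == ngrp], lab_idx[grp == 1L])
    runs_idx <- c(lapply(seq_len(ngrp)[-c(1L, ngrp)],
                         function(gq) lab_idx[grp == gq]),
                  list(merged))
  } else {
    runs_idx <- lapply(seq_len(ngrp), function(gq) lab_idx[grp == gq])
  }
  lapply(runs_idx, function(ii) {
    list(side = line[ii[1]],
         edge_pos = ii,
         content = unlist(labels[ii], use.names = FALSE),
         m = length(ii))
  })
}

indel_potential_value <- function(Lambda) {
  if (Lambda == 0L) 0L else as.integer(ceiling((Lambda + 1) / 2))
}

#' Run count of a cycle
#'
#' The number of maximal subpaths of the cycle in which the first and last
#' edges are labeled and all labeled edges belong to the same genome.
#'
#' @param cycle A cycle of a [build_diagram()] result.
#' @return Integer run count \eqn{\Lambda(C)}.
#' @export
count_runs <- function(cycle) {
  cycle$Lambda
}

#' Indel-potential of a cycle
#'
#' The minimum number of runs obtainable when DCJ-sorting the cycle with
#' split operations: 0 for a clean cycle, otherwise
#' \eqn{\lceil(\Lambda+1)/2\rceil}.
#'
#' @param cycle A cycle, or an integer run count.
#' @return Integer \eqn{\lambda(C)}.
#' @export
indel_potential <- function(cycle) {
  if (is.numeric(cycle)) return(indel_potential_value(as.integer(cycle)))
  indel_potential_value(cycle$Lambda)
}

#' Is a DCJ-unsorted cycle bad?
#'
#' A DCJ-unsorted cycle is bad when it has no pair of orange edges with
#' opposite traversal orientations, so no inversion applied to its orange
#' edges can split it.
#'
#' @param cycle A cycle with more than one orange edge.
#' @return Logical flag.
#' @export
cycle_is_bad <- function(cycle) {
  if (cycle$n_orange < 2L)
    stop_invindel("2-cycles are DCJ-sorted; badness is not defined for them",
                  "invindel_not_applicable")
  length(unique(cycle$orange_dir)) == 1L
}

sum_lambda <- function(R) {
  sum(vapply(R$cycles, `[[`, integer(1), "lambda"))
}

n_cycles <- function(R) length(R$cycles)

#' Find the cycle containing a given upper-line extremity
#'
#' @param R A relational diagram.
#' @param ext Extremity string such as `"a.h"` (head of marker a).
#' @return The cycle containing that vertex of genome A's line.
#' @export
cycle_through <- function(R, ext) {
  pos <- match(ext, R$lineA$verts)
  if (is.na(pos))
    stop_invindel(sprintf("no upper-line vertex '%s'", ext), "invindel_format")
  eidx <- as.integer(ceiling(pos / 2))
  for (cy in R$cycles) {
    sel <- cy$edges$line == "A" & cy$edges$idx == eidx
    if (any(sel)) return(cy)
  }
  stop("internal error: vertex not on any cycle")   # nocov
}

#' @export
print.relational_diagram <- function(x, ...) {
  cat(sprintf("Relational diagram: |G| = %d, start marker '%s', %d cycle(s)\n",
              x$n, x$start, length(x$cycles)))
  for (cy in x$cycles) {
    cat(sprintf("  C%d: %d orange edge(s), Lambda = %d, lambda = %d%s\n",
                cy$id, cy$n_orange, cy$Lambda, cy$lambda,
                if (cy$n_orange >= 2L)
                  if (cycle_is_bad(cy)) ", bad" else ", good"
                else ""))
  }
  invisible(x)
}
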