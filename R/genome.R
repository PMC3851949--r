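# Circular genomes of signed, duplicate-free markers.
#
# A genome is stored as a linearization of the circle: parallel vectors of
# marker names and signs. Two genomes are considered equal when one marker
# list is a rotation of the other, or a rotation of the other's reversal with
# all signs flipped (reading the circle in the opposite direction).

MARKER_RE <- "^[A-Za-z0-9_]+$"
BLOCK_PREFIX <- "__blk"

#' Construct a circular genome from signed marker tokens
#'
#' @param tokens Character vector of markers, each optionally prefixed with
#'   `-` to indicate reverse orientation, e.g. `c("a", "-b", "c")`.
#' @param label Free-text identifier for the genome.
#' @param allow_reserved Permit marker names starting with `__blk` (used
#'   internally for composite markers created by [collapse_unique_blocks()]).
#' @return An object of class `genome`.
#' @export
genome <- function(tokens, label = "", allow_reserved = FALSE) {
  tokens <- as.character(tokens)
  if (length(tokens) < 1L)
    stop_invindel("genome must contain at least one marker", "invindel_format")
  signs <- ifelse(startsWith(tokens, "-"), -1L, 1L)
  markers <- sub("^-", "", tokens)
  bad <- !grepl(MARKER_RE, markers)
  if (any(bad))
    stop_invindel(sprintf("invalid marker name(s): %s",
                          paste(markers[bad], collapse = ", ")),
                  "invindel_format")
  if (!allow_reserved && any(startsWith(markers, BLOCK_PREFIX)))
    stop_invindel(sprintf("marker names starting with '%s' are reserved",
                          BLOCK_PREFIX), "invindel_format")
  if (anyDuplicated(markers))
    stop_invindel(sprintf("duplicated marker(s): %s",
                          paste(unique(markers[duplicated(markers)]),
                                collapse = ", ")),
                  "invindel_duplicate_marker")
  structure(list(markers = markers, signs = as.integer(signs),
                 label = as.character(label)),
            class = "genome")
}

#' @export
length.genome <- function(x) length(x$markers)

genome_tokens <- function(g) {
  ifelse(g$signs < 0L, paste0("-", g$markers), g$markers)
}

#' @export
print.genome <- function(x, ...) {
  hdr <- if (nzchar(x$label)) paste0(">", x$label, "\n") else ""
  cat(hdr, "(", paste(genome_tokens(x), collapse = " "), ")\n", sep = "")
  invisible(x)
}

#' @export
format.genome <- function(x, ...) {
  paste0("(", paste(genome_tokens(x), collapse = " "), ")")
}

#' Parse a one-genome record
#'
#' Accepts the parenthesized notation `(a -b c)` as well as the GRIMM
#' circular dialect `a -b c @`, with an optional `>name` header line.
#' Linear GRIMM records (terminated by `$`) are rejected.
#'
#' @param text Character scalar (may contain newlines) holding one record.
#' @return A [genome()].
#' @export
parse_genome <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  label <- ""
  if (length(lines) && startsWith(lines[1], ">")) {
    label <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  body <- trimws(paste(lines, collapse = " "))
  if (!nzchar(body))
    stop_invindel("empty genome record", "invindel_format")
  if (grepl("\\$", body))
    stop_invindel("linear chromosomes ('$' terminator) are not supported",
                  "invindel_unsupported_structure")
  if (startsWith(body, "(")) {
    if (!endsWith(body, ")"))
      stop_invindel("unbalanced parentheses in genome record",
                    "invindel_format")
    body <- substr(body, 2L, nchar(body) - 1L)
  } else if (endsWith(body, "@")) {
    body <- sub("@$", "", body)
  } else {
    stop_invindel(
      "genome record must be '(...)' or terminated by '@' (circular)",
      "invindel_format")
  }
  toks <- strsplit(trimws(body), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks))
    stop_invindel("empty genome record", "invindel_format")
  genome(toks, label = label)
}

#' Read one circular genome from a text file
#'
#' @param path File with an optional `>name` header and one circular record.
#' @return A [genome()].
#' @export
read_genome <- function(path) {
  parse_genome(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Write a genome to a file or string
#'
#' @param g A [genome()].
#' @param path Output file; if `NULL` the record is returned as a string.
#' @param format `"paren"` for `(a -b)`, `"grimm"` for `a -b @`.
#' @export
write_genome <- function(g, path = NULL, format = c("paren", "grimm")) {
  format <- match.arg(format)
  body <- if (format == "paren") {
    paste0("(", paste(genome_tokens(g), collapse = " "), ")")
  } else {
    paste(c(genome_tokens(g), "@"), collapse = " ")
  }
  rec <- if (nzchar(g$label)) paste0(">", g$label, "\n", body) else body
  if (is.null(path)) return(rec)
  writeLines(rec, path)
  invisible(rec)
}

# Rotate the stored linearization so position `k` comes first.
rotate_genome <- function(g, k) {
  n <- length(g$markers)
  if (n == 1L || k == 1L) return(g)
  idx <- c(k:n, seq_len(k - 1L))
  g$markers <- g$markers[idx]
  g$signs <- g$signs[idx]
  g
}

# Read the circle in the opposite direction: reverse order, flip signs.
reflect_genome <- function(g) {
  g$markers <- rev(g$markers)
  g$signs <- -rev(g$signs)
  g
}

#' Canonical form of a circular genome
#'
#' The lexicographically least token sequence over all rotations of the
#' genome and all rotations of its reflection (reversed order, flipped
#' signs). Two genomes represent the same circular genome iff their
#' canonical forms are identical.
#'
#' @param g A [genome()].
#' @return Character vector of signed tokens.
#' @export
canonical_form <- function(g) {
  n <- length(g$markers)
  toks <- genome_tokens(g)
  rtoks <- genome_tokens(reflect_genome(g))
  best <- NULL
  best_key <- NULL
  for (k in seq_len(n)) {
    idx <- c(seq.int(k, n), seq_len(k - 1L))
    for (cand in list(toks[idx], rtoks[idx])) {
      key <- paste(cand, collapse = " ")
      if (is.null(best_key) || key < best_key) {
        best_key <- key
        best <- cand
      }
    }
  }
  best
}

#' Test circular genome equality
#'
#' @param a,b Genomes.
#' @return `TRUE` iff `a` and `b` are the same circular genome (up to
#'   rotation and reflection).
#' @export
genomes_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  identical(canonical_form(a), canonical_form(b))
}

#' Partition marker names into common and unique sets
#'
#' @param A,B Genomes.
#' @return List with sorted character vectors `common`, `onlyA`, `onlyB`.
#' @export
classify_markers <- function(A, B) {
  na <- A$markers
  nb <- B$markers
  list(common = sort(intersect(na, nb)),
       onlyA = sort(setdiff(na, nb)),
       onlyB = sort(setdiff(nb, na)))
}

#' Genome operations: inversions, deletions, insertions
#'
#' Construct an operation for [apply_operation()]. Cut sites for inversions
#' are between-marker indices on the current stored order: site `i` lies
#' after position `i`, so `inversion_op(i, j)` with `i < j` reverses (and
#' sign-flips) the segment at positions `i+1 .. j`.
#'
#' @param i,j Cut sites, `0 <= i < j <= length(genome)`.
#' @export
inversion_op <- function(i, j) {
  structure(list(kind = "inversion", i = as.integer(i), j = as.integer(j)),
            class = "genome_op")
}

#' @rdname inversion_op
#' @param markers For deletions, the names of the contiguous block to remove.
#' @export
deletion_op <- function(markers) {
  structure(list(kind = "deletion", markers = as.character(markers)),
            class = "genome_op")
}

#' @rdname inversion_op
#' @param tokens For insertions, signed tokens of the block to insert.
#' @param after Marker name after which the block is spliced.
#' @export
insertion_op <- function(tokens, after) {
  structure(list(kind = "insertion", tokens = as.character(tokens),
                 after = as.character(after)),
            class = "genome_op")
}

#' Apply an operation to a genome
#'
#' @param g A [genome()].
#' @param op An operation from [inversion_op()], [deletion_op()] or
#'   [insertion_op()].
#' @param common Optional character vector of protected (common) marker
#'   names; a deletion touching one of them raises a model-violation error.
#' @return The transformed genome.
#' @export
apply_operation <- function(g, op, common = NULL) {
  stopifnot(inherits(op, "genome_op"))
  n <- length(g$markers)
  switch(op$kind,
    inversion = {
      i <- op$i; j <- op$j
      if (!(i >= 0L && j > i && j <= n))
        stop_invindel("invalid inversion cut sites", "invindel_model_violation")
      seg <- (i + 1L):j
      g$markers[seg] <- rev(g$markers[seg])
      g$signs[seg] <- -rev(g$signs[seg])
      g
    },
    deletion = {
      del <- op$markers
      if (!is.null(common) && length(intersect(del, common)))
        stop_invindel("deletion would remove a common marker",
                      "invindel_model_violation")
      pos <- match(del, g$markers)
      if (anyNA(pos))
        stop_invindel("deletion block contains absent markers",
                      "invindel_model_violation")
      if (length(pos) >= n)
        stop_invindel("cannot delete the whole genome",
                      "invindel_model_violation")
      if (!circularly_contiguous(pos, n))
        stop_invindel("deletion block is not contiguous",
                      "invindel_model_violation")
      g$markers <- g$markers[-pos]
      g$signs <- g$signs[-pos]
      g
    },
    insertion = {
      signs <- ifelse(startsWith(op$tokens, "-"), -1L, 1L)
      names_ <- sub("^-", "", op$tokens)
      if (any(names_ %in% g$markers) || anyDuplicated(names_))
        stop_invindel("insertion would create a duplicated marker",
                      "invindel_model_violation")
      p <- match(op$after, g$markers)
      if (is.na(p))
        stop_invindel(sprintf("insertion site marker '%s' not found", op$after),
                      "invindel_model_violation")
      g$markers <- append(g$markers, names_, after = p)
      g$signs <- append(g$signs, as.integer(signs), after = p)
      g
    },
    stop_invindel("unknown operation kind", "invindel_model_violation"))
}

# Are positions `pos` contiguous on a circle of size n (possibly wrapping)?
circularly_contiguous <- function(pos, n) {
  k <- length(pos)
  if (k <= 1L) return(TRUE)
  pos <- sort(pos)
  if (all(diff(pos) == 1L)) return(TRUE)
  # wrapping: one gap allowed, covering n
  gaps <- diff(c(pos, pos[1] + n))
  sum(gaps != 1L) == 1L
}

#' Collapse maximal runs of unique markers into composite markers
#'
#' Every maximal run of consecutive markers unique to one genome is replaced
#' by a single fresh composite marker (`__blkA1`, `__blkB1`, ...), so that in
#' the relational diagram every edge label carries at most one marker. The
#' cycle structure and per-cycle run counts of the diagram are unchanged.
#'
#' @param A,B Genomes with at least one common marker.
#' @return List with genomes `A`, `B` and `map`, a named list giving each
#'   composite marker's original signed tokens (in the composite's direct
#'   orientation).
#' @export
collapse_unique_blocks <- function(A, B) {
  part <- classify_markers(A, B)
  if (!length(part$common))
    stop_invindel("collapse requires at least one common marker",
                  "invindel_trivial_case")
  map <- list()
  do_one <- function(g, unique_set, prefix) {
    if (!length(unique_set)) return(g)
    # rotate so a common marker is first; unique runs then never wrap
    first_common <- which(!(g$markers %in% unique_set))[1]
    g <- rotate_genome(g, first_common)
    is_u <- g$markers %in% unique_set
    if (!any(is_u)) return(g)
    r <- rle(is_u)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep_markers <- character(0)
    keep_signs <- integer(0)
    blk <- 0L
    for (k in seq_along(r$values)) {
      idx <- starts[k]:ends[k]
      if (!r$values[k]) {
        keep_markers <- c(keep_markers, g$markers[idx])
        keep_signs <- c(keep_signs, g$signs[idx])
      } else if (length(idx) == 1L) {
        keep_markers <- c(keep_markers, g$markers[idx])
        keep_signs <- c(keep_signs, g$signs[idx])
      } else {
        blk <- blk + 1L
        nm <- paste0(BLOCK_PREFIX, prefix, blk)
        toks <- ifelse(g$signs[idx] < 0L, paste0("-", g$markers[idx]),
                       g$markers[idx])
        map[[nm]] <<- toks
        keep_markers <- c(keep_markers, nm)
        keep_signs <- c(keep_signs, 1L)
      }
    }
    genome(ifelse(keep_signs < 0L, paste0("-", keep_markers), keep_markers),
           label = g$label, allow_reserved = TRUE)
  }
  A2 <- do_one(A, part$onlyA, "A")
  B2 <- do_one(B, part$onlyB, "B")
  list(A = A2, B = B2, map = map)
}

#' Expand composite markers back to their original blocks
#'
#' @param g Genome possibly containing composite markers.
#' @param map Block map from [collapse_unique_blocks()].
#' @export
expand_blocks <- function(g, map) {
  if (!length(map)) return(g)
  out <- character(0)
  for (k in seq_along(g$markers)) {
    nm <- g$markers[k]
    if (!is.null(map[[nm]])) {
      toks <- map[[nm]]
      if (g$signs[k] < 0L) {
        flipped <- ifelse(startsWith(toks, "-"), sub("^-", "", toks),
                          paste0("-", toks))
        toks <- rev(flipped)
      }
      out <- c(out, toks)
    } else {
      out <- c(out, if (g$signs[k] < 0L) paste0("-", nm) else nm)
    }
  }
  genome(out, label = g$label)
}

#' Generate a random genome pair with known construction
#'
#' `B` is the identity genome `(g1 ... gn)`; `A` is obtained from `B` by
#' applying uniformly random inversions, after which unique markers with
#' random signs are inserted at uniform positions into `A` and `B`.
#'
#' @param n_common Number of common markers (>= 2).
#' @param n_inversions Number of random inversions applied to build `A`.
#' @param n_uniqueA,n_uniqueB Number of unique markers inserted into each
#'   genome.
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @param require_no_bad If `TRUE`, rejection-sample until the relational
#'   diagram of the pair has no bad component.
#' @param max_tries Bound on rejection-sampling draws.
#' @return List with genomes `A` and `B`.
#' @export
random_genome_pair <- function(n_common, n_inversions = 0L,
                               n_uniqueA = 0L, n_uniqueB = 0L,
                               seed = NULL, require_no_bad = FALSE,
                               max_tries = 500L) {
  if (n_common < 2L)
    stop_invindel("n_common must be >= 2", "invindel_format")
  with_seed(seed, {
    for (try in seq_len(if (require_no_bad) max_tries else 1L)) {
      pair <- draw_genome_pair(n_common, n_inversions, n_uniqueA, n_uniqueB)
      if (!require_no_bad) return(pair)
      comps <- find_components(build_diagram(pair$A, pair$B))
      if (!any(vapply(comps, function(k) k$class == "bad", logical(1))))
        return(pair)
    }
    stop_invindel("no pair without bad components found within max_tries",
                  "invindel_generator_exhausted")
  })
}

draw_genome_pair <- function(n_common, n_inversions, n_uniqueA, n_uniqueB) {
  B <- genome(paste0("g", seq_len(n_common)), label = "B")
  A <- B
  A$label <- "A"
  for (k in seq_len(n_inversions)) {
    s <- sort(sample.int(n_common + 1L, 2L) - 1L)   # sites 0..n
    if (s[1] == 0L && s[2] == n_common) s[2] <- n_common - 1L
    if (s[1] == s[2]) s[2] <- s[1] + 1L
    A <- apply_operation(A, inversion_op(s[1], s[2]))
  }
  insert_uniques <- function(g, k, prefix) {
    for (u in seq_len(k)) {
      tok <- paste0(if (runif(1) < 0.5) "-" else "", prefix, u)
      pos <- sample.int(length(g$markers), 1L)
      g <- apply_operation(g, insertion_op(tok, g$markers[pos]))
    }
    g
  }
  A <- insert_uniques(A, n_uniqueA, "x")
  B <- insert_uniques(B, n_uniqueB, "y")
  list(A = A, B = B)
}
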