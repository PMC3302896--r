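#' @title Protein records and strand tables
#' @description Internal constructors and helpers for the shared data model.
#' All coordinates are 1-based and inclusive (DSSP convention).
#' @name protein-model
NULL

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# normalize a raw sequence string: uppercase, strip whitespace,
# map non-standard residues to 'X'
normalize_sequence <- function(x) {
  x <- toupper(gsub("[[:space:]]", "", x))
  chars <- strsplit(x, "")[[1]]
  bad <- !(chars %in% c(STANDARD_AA, "X", "B", "Z", "J", "U", "O", "*", "-", "."))
  if (any(bad)) {
    stop("illegal residue character(s): ",
         paste(unique(chars[bad]), collapse = " "))
  }
  chars[!(chars %in% STANDARD_AA)] <- "X"
  paste(chars, collapse = "")
}

#' Construct a protein record
#'
#' @param id identifier string.
#' @param sequence amino-acid string (one-letter codes; anything outside the
#'   20 standard codes becomes `X`).
#' @param strands optional data frame with columns `start`, `end` (1-based,
#'   inclusive); strand indices are always re-derived from sequence order.
#' @param helix_segments optional data frame with columns `start`, `end`.
#' @return An object of class `protein_record`: a list with elements `id`,
#'   `sequence`, `strands` (data frame: `index`, `start`, `end`, `length`,
#'   `residues`), `helix_segments`, `n_residues`, `f_alpha`, `f_beta`.
#' @export
protein_record <- function(id, sequence, strands = NULL, helix_segments = NULL) {
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  rec <- structure(
    list(id = as.character(id), sequence = sequence,
         strands = empty_strand_table(), helix_segments = helix_segments,
         n_residues = n, f_alpha = 0, f_beta = 0),
    class = "protein_record")
  if (!is.null(helix_segments) && nrow(helix_segments)) {
    rec$f_alpha <- sum(helix_segments$end - helix_segments$start + 1L) / n
  }
  if (!is.null(strands) && nrow(strands)) rec <- attach_strands(rec, strands)
  rec
}

empty_strand_table <- function() {
  data.frame(index = integer(), start = integer(), end = integer(),
             length = integer(), residues = character(),
             stringsAsFactors = FALSE)
}

#' Attach a strand table to a protein record
#'
#' Strands are sorted by start position, indices re-assigned 1..N in sequence
#' order, residues sliced from the sequence, and `f_beta` recomputed.
#' Overlapping or out-of-range strands are rejected.
#'
#' @param protein a `protein_record`.
#' @param strands data frame with integer columns `start`, `end`.
#' @return The updated `protein_record`.
#' @export
attach_strands <- function(protein, strands) {
  stopifnot(inherits(protein, "protein_record"))
  st <- data.frame(start = as.integer(strands$start),
                   end = as.integer(strands$end))
  if (any(st$start > st$end)) {
    bad <- which(st$start > st$end)[1]
    stop(sprintf("strand with start > end: (%d, %d)", st$start[bad], st$end[bad]))
  }
  if (any(st$start < 1L) || any(st$end > protein$n_residues)) {
    stop("strand coordinates outside [1, ", protein$n_residues, "]")
  }
  st <- st[order(st$start), , drop = FALSE]
  if (nrow(st) > 1L) {
    ov <- which(st$start[-1L] <= st$end[-nrow(st)])
    if (length(ov)) {
      stop(sprintf("overlapping strands: (%d,%d) and (%d,%d)",
                   st$start[ov[1]], st$end[ov[1]],
                   st$start[ov[1] + 1L], st$end[ov[1] + 1L]))
    }
  }
  st$index <- seq_len(nrow(st))
  st$length <- st$end - st$start + 1L
  st$residues <- vapply(seq_len(nrow(st)), function(r) {
    substr(protein$sequence, st$start[r], st$end[r])
  }, character(1))
  protein$strands <- st[, c("index", "start", "end", "length", "residues")]
  rownames(protein$strands) <- NULL
  protein$f_beta <- sum(st$length) / protein$n_residues
  if (protein$f_alpha + protein$f_beta > 1 + 1e-9) {
    stop("helix + strand residues exceed the sequence length")
  }
  protein
}

#' Drop strands below a minimum length
#'
#' Strands shorter than `min_len` are merged back into coil (removed) and the
#' remaining strands re-indexed. Used before modelling; parsers keep every
#' strand they see.
#'
#' @param protein a `protein_record`.
#' @param min_len minimum strand length to keep.
#' @return The filtered `protein_record`.
#' @export
filter_short_strands <- function(protein, min_len = 2L) {
  keep <- protein$strands$length >= min_len
  attach_strands(protein, protein$strands[keep, , drop = FALSE])
}

n_strands <- function(protein) nrow(protein$strands)

strand_residues <- function(protein, i) {
  strsplit(protein$strands$residues[i], "")[[1]]
}

# number of hydrophobic residues in strand i under the config's set
hydrophobic_count <- function(protein, i, cfg) {
  sum(strand_residues(protein, i) %in% cfg$hydrophobic_set)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d residues, %d strands (f_beta %.3f, f_alpha %.3f)\n",
              x$id, x$n_residues, n_strands(x), x$f_beta, x$f_alpha))
  if (n_strands(x)) {
    print(x$strands, row.names = FALSE)
  }
  invisible(x)
}

#' Construct a strand contact
#'
#' @param i,j strand indices, `i < j`.
#' @param orientation `"A"` (antiparallel) or `"P"` (parallel).
#' @param offset integer register shift of the chosen alignment.
#' @param residue_pairs two-column integer matrix of global residue positions
#'   `(k, l)` with `k < l`.
#' @return A list of class `strand_contact`.
#' @export
strand_contact <- function(i, j, orientation, offset, residue_pairs) {
  stopifnot(i < j, orientation %in% c("A", "P"))
  rp <- matrix(as.integer(residue_pairs), ncol = 2)
  stopifnot(all(rp[, 1] < rp[, 2]))
  structure(list(i = as.integer(i), j = as.integer(j),
                 orientation = orientation, offset = as.integer(offset),
                 residue_pairs = rp),
            class = "strand_contact")
}

#' Construct a sheet topology
#'
#' @param contacts list of `strand_contact` objects.
#' @param objective total corrected contact potential of the topology.
#' @param rank 1-based rank in a returned list (`NA` if unranked).
#' @param n_strands total number of strands in the protein (used to derive
#'   the sheet partition; strands without contacts form singleton sheets).
#' @return A list of class `sheet_topology` with a derived `sheets` element:
#'   connected components of the strand-contact graph.
#' @export
sheet_topology <- function(contacts, objective = NA_real_, rank = NA_integer_,
                           n_strands = NULL) {
  if (is.null(n_strands)) {
    n_strands <- if (length(contacts)) {
      max(vapply(contacts, function(ct) ct$j, integer(1)))
    } else 0L
  }
  topo <- structure(list(contacts = contacts,
                         objective = objective,
                         rank = as.integer(rank),
                         n_strands = as.integer(n_strands),
                         sheets = NULL),
                    class = "sheet_topology")
  topo$sheets <- connected_components(contact_edges(topo), n_strands)
  topo
}

# contacts as a 2-column matrix of (i, j); zero rows for empty topologies
contact_edges <- function(topology) {
  if (!length(topology$contacts)) return(matrix(integer(), ncol = 2))
  t(vapply(topology$contacts, function(ct) c(ct$i, ct$j), integer(2)))
}

contact_orientations <- function(topology) {
  vapply(topology$contacts, function(ct) ct$orientation, character(1))
}

# connected components of an undirected graph given an edge matrix;
# returns a list of integer vectors (sorted), singletons included
connected_components <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges[r, 1]); rb <- find(edges[r, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

#' @export
print.sheet_topology <- function(x, ...) {
  cat(sprintf("<sheet_topology> rank %s, objective %.4f, %d contact(s), %d sheet(s)\n",
              ifelse(is.na(x$rank), "-", x$rank), x$objective,
              length(x$contacts), sum(lengths(x$sheets) > 1L)))
  for (ct in x$contacts) {
    cat(sprintf("  %d-%d %s offset %+d (%d residue pairs)\n",
                ct$i, ct$j,
                ifelse(ct$orientation == "A", "antiparallel", "parallel"),
                ct$offset, nrow(ct$residue_pairs)))
  }
  invisible(x)
}
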