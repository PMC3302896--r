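#' Best gapless alignment of two strands in one orientation
#'
#' Slides strand `j` across strand `i` (no gaps, no beta-bulges) and returns
#' the register maximizing the summed residue-pair potential. Offsets tie on
#' score are broken deterministically: smallest absolute offset first, then
#' the smaller signed offset.
#'
#' Offset convention: local position `a` of strand `i` pairs with local
#' position `b` of strand `j`, where `b = a + offset` for parallel and
#' `b = L_j + 1 - a + offset` for antiparallel alignments.
#'
#' @param strand_i,strand_j one-row strand entries (rows of
#'   `protein$strands`, or lists with `index`, `start`, `end`, `length`,
#'   `residues`). `strand_i` must precede `strand_j` in the sequence.
#' @param orientation `"A"` (antiparallel) or `"P"` (parallel).
#' @param table residue-pair potential matrix.
#' @param config a `sheet_config`; `min_overlap` and the locality weights
#'   are used.
#' @return A `pair_alignment` (list with `i`, `j`, `orientation`, `offset`,
#'   `pairs` (global residue position matrix), `raw_score`,
#'   `corrected_score`, `overlap_i`, `overlap_j`), or `NULL` when no offset
#'   yields at least `min_overlap` aligned pairs.
#' @export
align_pair <- function(strand_i, strand_j, orientation, table,
                       config = default_config()) {
  stopifnot(orientation %in% c("A", "P"))
  si <- as.list(strand_i); sj <- as.list(strand_j)
  stopifnot(si$index < sj$index)
  ri <- strsplit(si$residues, "")[[1]]
  rj <- strsplit(sj$residues, "")[[1]]
  Li <- length(ri); Lj <- length(rj)
  min_ov <- config$min_overlap
  if (min(Li, Lj) < min_ov) return(NULL)

  best <- NULL
  for (o in seq.int(-(Li + Lj), Li + Lj)) {
    if (orientation == "P") {
      amin <- max(1L, 1L - o); amax <- min(Li, Lj - o)
    } else {
      amin <- max(1L, 1L + o); amax <- min(Li, Lj + o)
    }
    ov <- amax - amin + 1L
    if (ov < min_ov) next
    a <- seq.int(amin, amax)
    b <- if (orientation == "P") a + o else Lj + 1L - a + o
    sc <- sum(pot_lookup(table, ri[a], rj[b]))
    better <- is.null(best) ||
      sc > best$raw_score + 1e-12 ||
      (abs(sc - best$raw_score) <= 1e-12 &&
         (abs(o) < abs(best$offset) ||
            (abs(o) == abs(best$offset) && o < best$offset)))
    if (better) {
      best <- list(offset = o, raw_score = sc, a = a, b = b)
    }
  }
  if (is.null(best)) return(NULL)
  pairs <- cbind(si$start + best$a - 1L, sj$start + best$b - 1L)
  structure(list(
    i = si$index, j = sj$index, orientation = orientation,
    offset = best$offset,
    pairs = pairs,
    raw_score = best$raw_score,
    corrected_score = locality_correct(best$raw_score, si$index, sj$index,
                                       config, orientation),
    overlap_i = length(best$a), overlap_j = length(best$b)),
    class = "pair_alignment")
}

#' Locality correction of a raw pair score
#'
#' Database-derived pair potentials over-represent local (sequence-adjacent)
#' strand contacts; the raw score is multiplied by a per-separation weight
#' (below 1 for separation 1 by default, 1 beyond).
#'
#' @param raw_score raw alignment score.
#' @param i,j strand indices with `i < j`.
#' @param config a `sheet_config` (supplies `locality_weights`).
#' @param orientation contact orientation; a separate parallel weight vector
#'   is used if configured, otherwise the shared one.
#' @return The corrected score.
#' @export
locality_correct <- function(raw_score, i, j, config = default_config(),
                             orientation = "A") {
  stopifnot(i < j)
  raw_score * locality_weight(config, j - i, orientation)
}

#' Score all strand pairs of a protein
#'
#' Computes, for every unordered strand pair and both orientations, the best
#' gapless alignment and its locality-corrected score. Pairs admitting no
#' alignment of at least `min_overlap` residues are omitted.
#'
#' @param protein a `protein_record` with at least 3 strands.
#' @param table residue-pair potential matrix.
#' @param config a `sheet_config`.
#' @return An object of class `scored_pairs`: a list with `alignments`
#'   (named `"i:j:O"`), `n_strands` and the strand table. Access entries
#'   with [sp_get()]; `(i, j)` and `(j, i)` resolve identically.
#' @export
score_all_pairs <- function(protein, table, config = default_config()) {
  N <- n_strands(protein)
  if (N < 3L) {
    stop("topology prediction requires at least 3 strands; got ", N)
  }
  alignments <- list()
  for (i in seq_len(N - 1L)) {
    for (j in seq.int(i + 1L, N)) {
      for (o in c("A", "P")) {
        al <- align_pair(protein$strands[i, ], protein$strands[j, ], o,
                         table, config)
        if (!is.null(al)) alignments[[sp_key(i, j, o)]] <- al
      }
    }
  }
  structure(list(alignments = alignments, n_strands = N,
                 strands = protein$strands),
            class = "scored_pairs")
}

sp_key <- function(i, j, o) paste(min(i, j), max(i, j), o, sep = ":")

#' Look up a stored pair alignment
#'
#' @param sp a `scored_pairs` collection.
#' @param i,j strand indices (either order).
#' @param orientation `"A"` or `"P"`.
#' @return The stored `pair_alignment`, or `NULL` if the pair has no valid
#'   alignment in that orientation.
#' @export
sp_get <- function(sp, i, j, orientation) {
  sp$alignments[[sp_key(i, j, orientation)]]
}

# aligned positions of alignment `al` lying on strand `s` (global coords)
aligned_on <- function(al, s) {
  if (al$i == s) al$pairs[, 1] else if (al$j == s) al$pairs[, 2] else integer(0)
}

#' @export
print.scored_pairs <- function(x, ...) {
  cat(sprintf("<scored_pairs> %d strands, %d stored alignments\n",
              x$n_strands, length(x$alignments)))
  for (al in x$alignments) {
    cat(sprintf("  %d-%d %s offset %+d raw %.3f corrected %.3f (%d pairs)\n",
                al$i, al$j, al$orientation, al$offset, al$raw_score,
                al$corrected_score, nrow(al$pairs)))
  }
  invisible(x)
}
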