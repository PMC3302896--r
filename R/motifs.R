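#' Count distinct sheet motifs for n strands
#'
#' A motif is a linear order of the n strands within a sheet together with
#' the parallel/antiparallel orientation of each of the n-1 adjacent pairs.
#' A sheet read right-to-left is the same motif, so the reflection is
#' removed: `n!/2` distinct orders times `2^(n-1)` orientation vectors.
#'
#' @param n number of strands (n >= 2).
#' @return `n!/2 * 2^(n-1)` as a double (exact for the tabulated range).
#' @examples
#' count_motifs(3)  # 12
#' count_motifs(8)  # 2580480
#' @export
count_motifs <- function(n) {
  if (n < 2L) stop("motif counting needs n >= 2")
  factorial(n) / 2 * 2^(n - 1)
}

#' Enumerate all canonical sheet motifs
#'
#' Generates every motif exactly once in canonical form: of a strand order
#' and its reversal (with reversed orientation vector), the
#' lexicographically smaller `(order, orientations)` is kept.
#'
#' @param n number of strands (2 <= n <= cap).
#' @param cap refusal threshold; enumeration above it is refused with the
#'   count it would have produced (default 7, i.e. at most 161280 motifs).
#' @return A list of class `motif_set` with integer matrices `order`
#'   (m x n) and `orientation` (m x (n-1), 0 = antiparallel, 1 = parallel),
#'   one row per motif; `m = count_motifs(n)`.
#' @export
enumerate_motifs <- function(n, cap = 7L) {
  if (n < 2L) stop("motif enumeration needs n >= 2")
  if (n > cap) {
    stop(sprintf("enumeration refused for n = %d (> cap %d): it would produce %.0f motifs",
                 n, cap, count_motifs(n)))
  }
  perms <- permutations_of(n)
  keep <- vapply(seq_len(nrow(perms)), function(r) {
    lex_less(perms[r, ], rev(perms[r, ]))
  }, logical(1))
  perms <- perms[keep, , drop = FALSE]
  n_or <- 2^(n - 1)
  ors <- as.matrix(expand.grid(rep(list(0:1), n - 1))[, rev(seq_len(n - 1)), drop = FALSE])
  dimnames(ors) <- NULL
  order_m <- perms[rep(seq_len(nrow(perms)), each = n_or), , drop = FALSE]
  orient_m <- ors[rep(seq_len(n_or), times = nrow(perms)), , drop = FALSE]
  structure(list(order = order_m, orientation = orient_m, n = n),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set> n = %d: %d motifs\n", x$n, nrow(x$order)))
  invisible(x)
}

lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1]] < b[d[1]]
}

# all permutations of 1..n, lexicographic, as an n! x n matrix
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(first, rest[sub[r, ]])
    }
  }
  out
}

#' Exhaustive ranked search over all contact sets (oracle)
#'
#' Ground truth for [solve_ranked()] on small instances: enumerates every
#' assignment of orientations to subsets of the alignable strand pairs
#' (at most N-1 contacts, each pair in one orientation), filters through
#' the full post-hoc validator ([validate_topology()]), scores survivors by
#' the same corrected-potential objective and returns the top K.
#'
#' @param protein a `protein_record` (at most 6 strands).
#' @param scored_pairs output of [score_all_pairs()].
#' @param config a `sheet_config`.
#' @param K number of topologies to return (default `config$K`).
#' @return Ranked list of `sheet_topology`; attribute `n_feasible` records
#'   the total size of the feasible set.
#' @export
brute_force_rank <- function(protein, scored_pairs, config = default_config(),
                             K = config$K) {
  N <- n_strands(protein)
  if (N > 6L) stop("brute-force enumeration is limited to 6 strands")
  pairs <- utils::combn(N, 2L)
  # per unordered pair: available oriented alignments (NULL = skip choice)
  choices <- lapply(seq_len(ncol(pairs)), function(pc) {
    i <- pairs[1, pc]; j <- pairs[2, pc]
    Filter(Negate(is.null), list(sp_get(scored_pairs, i, j, "A"),
                                 sp_get(scored_pairs, i, j, "P")))
  })
  b <- suppressWarnings(hbond_bounds(protein, config))
  feasible <- list()
  sel <- vector("list", ncol(pairs))

  recurse <- function(pc, n_edges, deg, npair_sum) {
    if (n_edges > N - 1L || npair_sum > b[["hi"]]) return()
    if (pc > ncol(pairs)) {
      if (any(deg < 1L) || npair_sum < b[["lo"]]) return()
      alns <- Filter(Negate(is.null), sel)
      contacts <- lapply(alns, function(al)
        strand_contact(al$i, al$j, al$orientation, al$offset, al$pairs))
      topo <- sheet_topology(contacts,
                             objective = sum(vapply(alns, `[[`, numeric(1),
                                                    "corrected_score")),
                             n_strands = N)
      rep <- validate_topology(topo, protein, config, scored_pairs)
      if (rep$pass) feasible[[length(feasible) + 1L]] <<- topo
      return()
    }
    i <- pairs[1, pc]; j <- pairs[2, pc]
    # upper bound on degree still achievable for earlier strands is not
    # tracked; the cheap caps above prune enough at these sizes
    sel[pc] <<- list(NULL)
    recurse(pc + 1L, n_edges, deg, npair_sum)
    if (deg[i] < config$max_contacts_per_strand &&
        deg[j] < config$max_contacts_per_strand) {
      for (al in choices[[pc]]) {
        deg2 <- deg; deg2[i] <- deg2[i] + 1L; deg2[j] <- deg2[j] + 1L
        sel[[pc]] <<- al
        recurse(pc + 1L, n_edges + 1L, deg2, npair_sum + nrow(al$pairs))
        sel[pc] <<- list(NULL)
      }
    }
  }
  recurse(1L, 0L, integer(N), 0L)

  objs <- vapply(feasible, `[[`, numeric(1), "objective")
  ord <- order(-objs)
  top <- feasible[ord[seq_len(min(K, length(ord)))]]
  for (r in seq_along(top)) top[[r]]$rank <- r
  attr(top, "n_feasible") <- length(feasible)
  top
}
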