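# Shared in-code fixtures and independent oracles for the test suite.

# constant potential table (every standard residue pair scores `val`)
uniform_table <- function(val = 1) {
  aa <- rownames(sheettopo::default_potential())
  m <- matrix(val, 20, 20, dimnames = list(aa, aa))
  attr(m, "name") <- "uniform"
  m
}

# a table that scores only specific residue pairs
pair_table <- function(..., base = 0) {
  m <- uniform_table(base)
  entries <- list(...)
  for (e in entries) {           # e = list(a, b, score)
    m[e[[1]], e[[2]]] <- e[[3]]
    m[e[[2]], e[[1]]] <- e[[3]]
  }
  m
}

# protein with strands of the given residue strings, separated by G-loops
toy_protein <- function(strand_seqs, loop = "GGG", id = "toy") {
  seqs <- unlist(strand_seqs)
  full <- paste0(loop, paste(seqs, collapse = loop), loop)
  starts <- integer(length(seqs))
  pos <- nchar(loop)
  for (s in seq_along(seqs)) {
    starts[s] <- pos + 1L
    pos <- pos + nchar(seqs[s]) + nchar(loop)
  }
  protein_record(id, full,
                 strands = data.frame(start = starts,
                                      end = starts + nchar(seqs) - 1L))
}

# independent exhaustive-offset alignment oracle: double loop over every
# anchor pairing, no shared code with align_pair
oracle_best_alignment <- function(ri, rj, orientation, table, min_overlap = 2) {
  Li <- length(ri); Lj <- length(rj)
  best <- NULL
  score_of <- function(a, b) {
    s <- 0
    for (k in seq_along(a)) {
      x <- ri[a[k]]; y <- rj[b[k]]
      s <- s + if (x %in% rownames(table) && y %in% colnames(table))
        table[x, y] else 0
    }
    s
  }
  for (o in -(Li + Lj):(Li + Lj)) {
    aa <- integer(0); bb <- integer(0)
    for (a in seq_len(Li)) {
      b <- if (orientation == "P") a + o else Lj + 1L - a + o
      if (b >= 1 && b <= Lj) { aa <- c(aa, a); bb <- c(bb, b) }
    }
    if (length(aa) < min_overlap) next
    sc <- score_of(aa, bb)
    if (is.null(best) || sc > best$score + 1e-12) {
      best <- list(score = sc, offset = o)
    }
  }
  best
}

# hand-build a contact (residue pairs given in strand-local coordinates)
manual_contact <- function(protein, i, j, orientation, a_local, b_local) {
  st <- protein$strands
  strand_contact(i, j, orientation, 0L,
                 cbind(st$start[i] + a_local - 1L, st$start[j] + b_local - 1L))
}

# a config with every budget-style constraint relaxed, used to isolate
# single constraint families in violation tests
relaxed_config <- function(...) {
  default_config(budget_lo_min = 0, budget_lo_slack = 1000L,
                 budget_hi_factor = 1000, hbond_tolerance = 0.99,
                 nonlocal_threshold = 99L, ...)
}

# minimal DSSP file text for a sequence and per-residue structure string
make_dssp_text <- function(seq, ss) {
  aa <- strsplit(seq, "")[[1]]
  st <- strsplit(ss, "")[[1]]
  stopifnot(length(aa) == length(st))
  c("==== Secondary Structure Definition, synthetic test file ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    vapply(seq_along(aa), function(i)
      sprintf("%5d%5d A %s  %s", i, i, aa[i], st[i]), character(1)))
}

# topology from an edge matrix with full-width identity registers
mk_edge_topology <- function(protein, edges, orientations = NULL) {
  if (is.null(orientations)) orientations <- rep("A", nrow(edges))
  cts <- lapply(seq_len(nrow(edges)), function(r) {
    i <- edges[r, 1]; j <- edges[r, 2]
    L <- min(protein$strands$length[i], protein$strands$length[j])
    manual_contact(protein, i, j, orientations[r], seq_len(L),
                   if (orientations[r] == "P") seq_len(L) else rev(seq_len(L)))
  })
  sheet_topology(cts, n_strands = nrow(protein$strands))
}

# exhaustive bipartiteness oracle over an edge list on m nodes
oracle_bipartite <- function(m, edges) {
  if (m == 0L || nrow(edges) == 0L) return(TRUE)
  cols <- as.matrix(expand.grid(rep(list(0:1), m)))
  ok <- rep(TRUE, nrow(cols))
  for (r in seq_len(nrow(edges))) {
    ok <- ok & (cols[, edges[r, 1]] != cols[, edges[r, 2]])
  }
  any(ok)
}
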