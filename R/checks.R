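#' Find simple cycles in the strand-contact graph
#'
#' Strands are nodes, active contacts are edges. Any simple cycle of length
#' at least 3 corresponds to a barrel-like (cyclically closed) arrangement
#' and is rejected by the ranked-solution loop.
#'
#' @param topology a `sheet_topology`.
#' @return A list of integer vectors, each a cycle as an ordered strand
#'   list (smallest member first, orientation-canonical); empty for
#'   forests.
#' @export
find_cycles <- function(topology) {
  edges <- contact_edges(topology)
  if (!nrow(edges)) return(list())
  n <- topology$n_strands
  adj <- lapply(seq_len(n), function(s)
    sort(unique(c(edges[edges[, 1] == s, 2], edges[edges[, 2] == s, 1]))))
  cycles <- list()
  # enumerate each cycle once: start at its smallest vertex, walk only
  # through larger vertices, and fix direction by second < last
  path <- integer(0)
  dfs <- function(start, v) {
    path[length(path) + 1L] <<- v
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 3L) {
        if (path[2L] < path[length(path)]) {
          cycles[[length(cycles) + 1L]] <<- path
        }
      } else if (w > start && !(w %in% path)) {
        dfs(start, w)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) dfs(s, s)
  cycles
}

# interval of aligned positions of contact `ct` on strand `s`
contact_interval_on <- function(ct, s) {
  pos <- if (ct$i == s) ct$residue_pairs[, 1] else ct$residue_pairs[, 2]
  range(pos)
}

#' Build the contact-incompatibility graph of a topology
#'
#' Nodes are contacts; two contacts are connected when they share a strand
#' and either have opposing orientations or their aligned footprints on the
#' shared strand share at least one residue. A proper 2-coloring of this
#' graph is a consistent assignment of contacts to the two faces of every
#' strand.
#'
#' @param topology a `sheet_topology`.
#' @return A two-column matrix of contact-index pairs (the edges).
#' @export
incompatibility_graph <- function(topology) {
  cts <- topology$contacts
  m <- length(cts)
  edges <- matrix(integer(), ncol = 2)
  if (m < 2L) return(edges)
  for (u in seq_len(m - 1L)) {
    for (w in seq.int(u + 1L, m)) {
      shared <- intersect(c(cts[[u]]$i, cts[[u]]$j), c(cts[[w]]$i, cts[[w]]$j))
      if (!length(shared)) next
      incompatible <- cts[[u]]$orientation != cts[[w]]$orientation
      if (!incompatible) {
        for (s in shared) {
          iu <- contact_interval_on(cts[[u]], s)
          iw <- contact_interval_on(cts[[w]], s)
          if (min(iu[2], iw[2]) >= max(iu[1], iw[1])) {
            incompatible <- TRUE; break
          }
        }
      }
      if (incompatible) edges <- rbind(edges, c(u, w))
    }
  }
  edges
}

#' Check two-colorability of the contact-incompatibility graph
#'
#' Breadth-first 2-coloring. Success yields a face assignment for every
#' contact; failure yields an odd cycle of mutually incompatible contacts
#' as witness.
#'
#' @param topology a `sheet_topology`.
#' @return A list: `ok` (logical); on success `coloring` (integer vector in
#'   \{1, 2\} per contact), on failure `witness` (contact indices of an odd
#'   cycle).
#' @export
is_two_colorable <- function(topology) {
  m <- length(topology$contacts)
  if (m == 0L) return(list(ok = TRUE, coloring = integer(0)))
  edges <- incompatibility_graph(topology)
  adj <- lapply(seq_len(m), function(u)
    c(edges[edges[, 1] == u, 2], edges[edges[, 2] == u, 1]))
  color <- rep(NA_integer_, m)
  parent <- rep(NA_integer_, m)
  for (root in seq_len(m)) {
    if (!is.na(color[root])) next
    color[root] <- 1L
    queue <- root
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[u]]) {
        if (is.na(color[w])) {
          color[w] <- 3L - color[u]
          parent[w] <- u
          queue <- c(queue, w)
        } else if (color[w] == color[u]) {
          # odd cycle: paths from u and w to their common ancestor
          pu <- u; pw <- w
          anc_u <- pu
          while (!is.na(parent[pu])) { pu <- parent[pu]; anc_u <- c(anc_u, pu) }
          path_w <- pw
          while (!(pw %in% anc_u) && !is.na(parent[pw])) {
            pw <- parent[pw]; path_w <- c(path_w, pw)
          }
          meet <- pw
          path_u <- anc_u[seq_len(which(anc_u == meet))]
          witness <- c(rev(path_u), path_w[path_w != meet])
          return(list(ok = FALSE, witness = unique(witness)))
        }
      }
    }
  }
  list(ok = TRUE, coloring = color)
}

#' Re-check every constraint family on a topology
#'
#' Post-hoc validation outside the solver: each constraint family is
#' evaluated combinatorially on the realized contacts. A topology returned
#' by [solve_ranked()] must pass all checks.
#'
#' @param topology a `sheet_topology`.
#' @param protein the `protein_record` it was predicted for.
#' @param config a `sheet_config`.
#' @param scored_pairs optional `scored_pairs`; when given, contact residue
#'   pairs are also checked against the stored best alignments (linking).
#' @return A list of class `topology_report`: `pass` (overall), `checks`
#'   (per family: `pass`, `witnesses`), `flags` (informational notes, e.g.
#'   contacts participating in more than one interlock).
#' @export
validate_topology <- function(topology, protein, config = default_config(),
                              scored_pairs = NULL) {
  N <- n_strands(protein)
  cts <- topology$contacts
  edges <- contact_edges(topology)
  ori <- contact_orientations(topology)
  L <- protein$strands$length
  checks <- list()
  flags <- character(0)
  fail <- function(witnesses) list(pass = length(witnesses) == 0L,
                                   witnesses = witnesses)

  # one orientation per pair (and no duplicated pair)
  keys <- if (nrow(edges)) paste(edges[, 1], edges[, 2]) else character(0)
  checks$orientation_exclusive <- fail(unique(keys[duplicated(keys)]))

  deg <- tabulate(edges, nbins = N)
  checks$strand_degree_max <-
    fail(which(deg > config$max_contacts_per_strand))
  checks$strand_degree_min <- fail(which(deg < 1L))
  checks$total_contacts <-
    fail(if (nrow(edges) > N - 1L) sprintf("%d > %d", nrow(edges), N - 1L))

  # residue degree <= 2
  allpos <- unlist(lapply(cts, function(ct) as.vector(ct$residue_pairs)))
  over <- if (length(allpos)) {
    tb <- table(allpos); as.integer(names(tb)[tb > 2L])
  } else integer(0)
  checks$residue_degree <- fail(over)

  # residue budgets
  bad_budget <- character(0)
  for (s in seq_len(N)) {
    cover <- sum(vapply(cts, function(ct)
      if (ct$i == s || ct$j == s) nrow(ct$residue_pairs) else 0L, numeric(1)))
    b_lo <- max(config$budget_lo_min, L[s] - config$budget_lo_slack)
    b_hi <- config$budget_hi_factor * L[s]
    if (cover < b_lo || cover > b_hi) {
      bad_budget <- c(bad_budget,
                      sprintf("strand %d: %d outside [%d, %g]", s, cover, b_lo, b_hi))
    }
  }
  checks$residue_budget <- fail(bad_budget)

  # triple overlap on a common strand
  bad_triple <- character(0)
  for (s in seq_len(N)) {
    inc <- which(vapply(cts, function(ct) ct$i == s || ct$j == s, logical(1)))
    if (length(inc) < 3L) next
    for (tri in utils::combn(inc, 3L, simplify = FALSE)) {
      ivals <- lapply(cts[tri], contact_interval_on, s = s)
      if (all_pairwise_overlap(ivals)) {
        bad_triple <- c(bad_triple, sprintf("strand %d: contacts %s", s,
                                            paste(tri, collapse = ",")))
      }
    }
  }
  checks$triple_overlap <- fail(bad_triple)

  # edge/neighbour cap
  bad_cap <- integer(0)
  for (s in seq_len(N)) {
    allowed <- allowed_partners(s, N)
    outside <- sum(vapply(cts, function(ct) {
      if (!(ct$i == s || ct$j == s)) return(FALSE)
      if (!(ct$orientation %in% config$edge_cap_orientations)) return(FALSE)
      other <- if (ct$i == s) ct$j else ct$i
      !(other %in% allowed)
    }, logical(1)))
    if (outside > 2L) bad_cap <- c(bad_cap, s)
  }
  checks$edge_neighbor_cap <- fail(bad_cap)

  # non-local support
  thr <- config$nonlocal_threshold
  active_pairs <- if (nrow(edges)) {
    unique(data.frame(i = edges[, 1], j = edges[, 2]))
  } else data.frame(i = integer(), j = integer())
  has_contact <- function(a, b) {
    a0 <- min(a, b); b0 <- max(a, b)
    any(active_pairs$i == a0 & active_pairs$j == b0)
  }
  bad_nl <- character(0)
  for (r in seq_len(nrow(active_pairs))) {
    i <- active_pairs$i[r]; j <- active_pairs$j[r]
    if (j - i < thr) next
    nb_i <- resolved_neighbors(protein, i, config)
    nb_j <- resolved_neighbors(protein, j, config)
    supp <- rbind(cbind(i, nb_i), cbind(j, nb_j))
    if (j - i == thr) supp <- rbind(supp, c(i, j - 1L), c(i + 1L, j))
    ok <- FALSE
    for (rr in seq_len(nrow(supp))) {
      a <- supp[rr, 1]; b <- supp[rr, 2]
      if (a == b || (min(a, b) == i && max(a, b) == j)) next
      if (has_contact(a, b)) { ok <- TRUE; break }
    }
    if (!ok) bad_nl <- c(bad_nl, sprintf("%d-%d", i, j))
  }
  checks$nonlocal_support <- fail(bad_nl)

  # pretzel quartets
  bad_pz <- character(0)
  if (N >= 4L && nrow(active_pairs) >= 3L) {
    for (q in utils::combn(N, 4L, simplify = FALSE)) {
      for (chain in list(rbind(q[c(1, 3)], q[c(1, 4)], q[c(2, 4)]),
                         rbind(q[c(1, 3)], q[c(2, 3)], q[c(2, 4)]))) {
        if (all(vapply(seq_len(3), function(rr)
          has_contact(chain[rr, 1], chain[rr, 2]), logical(1)))) {
          bad_pz <- c(bad_pz, paste(q, collapse = "-"))
        }
      }
    }
  }
  checks$pretzel <- fail(unique(bad_pz))

  # interlock requirement (and multiplicity flag)
  nl <- active_pairs[active_pairs$j - active_pairs$i >= thr, , drop = FALSE]
  bad_il <- character(0)
  if (nrow(nl)) {
    for (r in seq_len(nrow(nl))) {
      i <- nl$i[r]; k <- nl$j[r]
      mates <- sum(vapply(seq_len(nrow(nl)), function(r2) {
        if (r2 == r) return(FALSE)
        jj <- nl$i[r2]; ll <- nl$j[r2]
        (i < jj && jj < k && k < ll) || (jj < i && i < ll && ll < k)
      }, logical(1)))
      if (mates == 0L) bad_il <- c(bad_il, sprintf("%d-%d", i, k))
      if (mates > 1L) {
        flags <- c(flags,
                   sprintf("non-local contact %d-%d lies in %d interlocks",
                           i, k, mates))
      }
    }
  }
  checks$interlock <- fail(bad_il)

  # terminal sets
  n_sets <- N %/% config$terminal_set_stride
  bad_ts <- character(0)
  if (n_sets >= 1L) {
    sorted <- terminal_sort_order(protein, config)
    for (k in seq_len(n_sets)) {
      members <- sorted[seq_len(2L * k)]
      got <- sum(deg[members] == 1L)
      if (got < k) {
        bad_ts <- c(bad_ts,
                    sprintf("set %d: %d of strands {%s} have one contact, need %d",
                            k, got, paste(members, collapse = ","), k))
      }
    }
  }
  checks$terminal_sets <- fail(bad_ts)

  # hydrogen-bond budget
  b <- suppressWarnings(hbond_bounds(protein, config))
  tot <- sum(vapply(cts, function(ct) nrow(ct$residue_pairs), numeric(1)))
  checks$hbond_budget <-
    fail(if (tot < b[["lo"]] || tot > b[["hi"]])
      sprintf("%d outside [%d, %d]", tot, b[["lo"]], b[["hi"]]))

  # barrel / coloring
  cyc <- find_cycles(topology)
  checks$acyclic <- fail(if (length(cyc))
    vapply(cyc, paste, character(1), collapse = "-"))
  col <- is_two_colorable(topology)
  checks$two_colorable <- fail(if (!col$ok)
    paste(col$witness, collapse = "-"))

  # linking: realized residue pairs equal the stored best alignments
  if (!is.null(scored_pairs)) {
    bad_link <- character(0)
    for (ct in cts) {
      al <- sp_get(scored_pairs, ct$i, ct$j, ct$orientation)
      if (is.null(al) || !identical(unname(al$pairs[order(al$pairs[, 1]), ]),
                                    unname(ct$residue_pairs[order(ct$residue_pairs[, 1]), ]))) {
        bad_link <- c(bad_link, sprintf("%d-%d:%s", ct$i, ct$j, ct$orientation))
      }
    }
    checks$linking <- fail(bad_link)
  }

  structure(list(pass = all(vapply(checks, `[[`, logical(1), "pass")),
                 checks = checks, flags = flags),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> overall: %s\n",
              if (x$pass) "PASS" else "FAIL"))
  for (nm in names(x$checks)) {
    ck <- x$checks[[nm]]
    cat(sprintf("  %-22s %s\n", nm, if (ck$pass) "pass"
                else paste("FAIL:", paste(ck$witnesses, collapse = "; "))))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Validation report as JSON
#'
#' @param report a `topology_report` from [validate_topology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(pass = report$pass,
         checks = lapply(report$checks, function(ck)
           list(status = if (ck$pass) "pass" else "fail",
                witnesses = as.character(ck$witnesses))),
         flags = report$flags),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
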