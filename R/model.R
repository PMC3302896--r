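#' @title The strand-contact optimization model
#'
#' @description
#' The topology model is a 0/1 linear program. For every strand pair with a
#' valid alignment there is one binary per orientation (antiparallel `y^A`,
#' parallel `y^P`); the objective maximizes the total locality-corrected
#' contact potential of the chosen contacts. Residue-level contact variables
#' are linked to the strand binaries by equality (the best register per pair
#' and orientation is fixed before the solve), so every residue-level
#' restriction reduces to a linear row over the strand binaries with
#' alignment-derived coefficients; the residue pairs themselves are
#' reconstructed from the stored alignments when a solution is read out.
#'
#' Constraint families:
#' * structural: one orientation per pair; residues in at most two contacts;
#'   1-3 contacts per strand; at most N-1 contacts in total (non-barrel).
#' * geometric: per-strand residue budgets; no three partners with mutually
#'   overlapping footprints on a common strand; strands with many contacts
#'   must keep one with a sequence neighbour or an edge strand.
#' * topological: non-local contacts require an active neighbour contact
#'   (hierarchical sheet growth); crossing "pretzel" quartets are forbidden;
#'   non-local contacts must be interlocked; the least hydrophobic, shortest
#'   strands are pushed to sheet edges (terminal sets).
#' * hydrogen-bond budget: the total number of realized residue pairs must
#'   match the expected backbone hydrogen-bond count of the strand residues
#'   within a relative tolerance.
#' @name topology-model
NULL

#' Build the topology optimization model
#'
#' Creates the variables and objective and installs every constraint family
#' ([add_structural_constraints()], [add_geometric_constraints()],
#' [add_topological_constraints()], [add_hbond_budget()]). Construction is
#' deterministic for fixed inputs.
#'
#' @param protein a `protein_record` with at least 3 strands.
#' @param scored_pairs output of [score_all_pairs()].
#' @param config a `sheet_config`.
#' @return A `topology_model` list: `vars` (variable table), `obj`,
#'   `rows` (linear constraints), plus references to its inputs.
#' @export
build_model <- function(protein, scored_pairs, config = default_config()) {
  N <- n_strands(protein)
  if (N < 3L) stop("topology prediction requires at least 3 strands; got ", N)

  vars <- list(); alns <- list()
  for (key in names(scored_pairs$alignments)) {
    al <- scored_pairs$alignments[[key]]
    vars[[length(vars) + 1L]] <- data.frame(
      name = key, kind = "y", i = al$i, j = al$j,
      orientation = al$orientation, score = al$corrected_score,
      npairs = nrow(al$pairs), stringsAsFactors = FALSE)
    alns[[length(alns) + 1L]] <- al
  }
  vars <- do.call(rbind, vars)
  for (s in seq_len(N)) {
    if (!any(vars$i == s | vars$j == s)) {
      stop("strand ", s, " has no alignable partner under min_overlap = ",
           config$min_overlap, "; the one-contact requirement cannot be met")
    }
  }

  # terminal-set indicator variables (z_s = 1 forces strand s to exactly
  # one contact); one set per `terminal_set_stride` strands
  n_sets <- N %/% config$terminal_set_stride
  sorted <- terminal_sort_order(protein, config)
  z_strands <- if (n_sets >= 1L) sorted[seq_len(min(2L * n_sets, N))] else integer(0)
  for (s in z_strands) {
    vars <- rbind(vars, data.frame(
      name = paste0("z:", s), kind = "z", i = s, j = NA_integer_,
      orientation = NA_character_, score = 0, npairs = 0L,
      stringsAsFactors = FALSE))
    alns[[nrow(vars)]] <- list(NULL)
  }
  rownames(vars) <- NULL

  model <- structure(list(
    protein = protein, scored_pairs = scored_pairs, config = config,
    vars = vars, alignments = alns, obj = vars$score,
    rows = list(), n_strands = N,
    terminal_order = sorted, n_terminal_sets = n_sets),
    class = "topology_model")
  model <- add_structural_constraints(model)
  model <- add_geometric_constraints(model, config)
  model <- add_topological_constraints(model, config)
  model <- add_hbond_budget(model, protein, config)
  model
}

add_row <- function(model, idx, coef, lo, hi, label) {
  stopifnot(length(idx) == length(coef))
  model$rows[[length(model$rows) + 1L]] <-
    list(idx = as.integer(idx), coef = as.numeric(coef),
         lo = lo, hi = hi, label = label)
  model
}

y_idx <- function(model) which(model$vars$kind == "y")

# indices of y variables touching strand s (optionally restricted to a
# partner set or orientation)
incident_vars <- function(model, s, partners = NULL, orientation = NULL) {
  v <- model$vars
  sel <- v$kind == "y" & (v$i == s | v$j == s)
  if (!is.null(partners)) {
    other <- ifelse(v$i == s, v$j, v$i)
    sel <- sel & other %in% partners
  }
  if (!is.null(orientation)) sel <- sel & v$orientation %in% orientation
  which(sel)
}

pair_vars <- function(model, i, j, orientation = NULL) {
  v <- model$vars
  sel <- v$kind == "y" & v$i == min(i, j) & v$j == max(i, j)
  if (!is.null(orientation)) sel <- sel & v$orientation %in% orientation
  which(sel)
}

#' Add the structural constraint family
#'
#' Orientation exclusivity per pair; each residue in at most two realized
#' contacts; 1 to `max_contacts_per_strand` contacts per strand; at most
#' N-1 contacts in total.
#'
#' @param model a `topology_model`.
#' @return The model with the rows appended.
#' @export
add_structural_constraints <- function(model) {
  v <- model$vars; N <- model$n_strands
  cfg <- model$config
  # one orientation per pair
  pairs <- unique(v[v$kind == "y", c("i", "j")])
  for (r in seq_len(nrow(pairs))) {
    ids <- pair_vars(model, pairs$i[r], pairs$j[r])
    if (length(ids) > 1L) {
      model <- add_row(model, ids, rep(1, length(ids)), -Inf, 1,
                       sprintf("orient_excl:%d-%d", pairs$i[r], pairs$j[r]))
    }
  }
  # residue degree <= 2: each strand residue may pair with at most two
  # partner residues (one per face)
  for (s in seq_len(N)) {
    ids <- incident_vars(model, s)
    if (length(ids) < 3L) next
    span <- model$protein$strands$start[s]:model$protein$strands$end[s]
    cover <- lapply(ids, function(vi) aligned_on(model$alignments[[vi]], s))
    for (p in span) {
      touch <- ids[vapply(cover, function(cc) p %in% cc, logical(1))]
      if (length(touch) >= 3L) {
        model <- add_row(model, touch, rep(1, length(touch)), -Inf, 2,
                         sprintf("residue_degree:%d", p))
      }
    }
  }
  # strand degree in [1, max]
  for (s in seq_len(N)) {
    ids <- incident_vars(model, s)
    model <- add_row(model, ids, rep(1, length(ids)),
                     1, cfg$max_contacts_per_strand,
                     sprintf("strand_degree:%d", s))
  }
  # total contacts <= N - 1 (non-barrel)
  ids <- y_idx(model)
  add_row(model, ids, rep(1, length(ids)), -Inf, N - 1, "total_contacts")
}

#' Add the geometric constraint family
#'
#' Residue budgets per strand (total partner residues aligned against strand
#' i must lie in `[B_lo(i), B_hi(i)]`); exclusion of three partners with
#' mutually overlapping footprints on a common strand; cap on contacts of a
#' strand with non-neighbour, non-edge strands.
#'
#' @param model a `topology_model`.
#' @param config a `sheet_config`.
#' @return The model with the rows appended.
#' @export
add_geometric_constraints <- function(model, config = model$config) {
  N <- model$n_strands
  L <- model$protein$strands$length
  # residue budgets
  for (s in seq_len(N)) {
    ids <- incident_vars(model, s)
    ov <- vapply(ids, function(vi) length(aligned_on(model$alignments[[vi]], s)),
                 numeric(1))
    b_lo <- max(config$budget_lo_min, L[s] - config$budget_lo_slack)
    b_hi <- config$budget_hi_factor * L[s]
    model <- add_row(model, ids, ov, b_lo, b_hi,
                     sprintf("residue_budget:%d", s))
  }
  # no wrap-around: for three partners of a common strand s whose aligned
  # footprints on s pairwise overlap, at most two of the contacts may be on
  for (s in seq_len(N)) {
    ids <- incident_vars(model, s)
    if (length(ids) < 3L) next
    partner <- ifelse(model$vars$i[ids] == s, model$vars$j[ids],
                      model$vars$i[ids])
    ivals <- lapply(ids, function(vi) range(aligned_on(model$alignments[[vi]], s)))
    partners <- sort(unique(partner))
    if (length(partners) < 3L) next
    trips <- utils::combn(partners, 3L)
    for (tcol in seq_len(ncol(trips))) {
      tri <- trips[, tcol]
      sets <- lapply(tri, function(p) which(partner == p))
      for (a in sets[[1]]) for (b in sets[[2]]) for (cc in sets[[3]]) {
        trio <- c(a, b, cc)
        if (all_pairwise_overlap(ivals[trio])) {
          model <- add_row(model, ids[trio], rep(1, 3), -Inf, 2,
                           sprintf("triple_overlap:%d|%d-%d-%d",
                                   s, tri[1], tri[2], tri[3]))
        }
      }
    }
  }
  # a strand may keep at most two contacts away from its sequence
  # neighbours and the chain-edge strands
  for (s in seq_len(N)) {
    allowed <- allowed_partners(s, N)
    ids <- incident_vars(model, s,
                         partners = setdiff(seq_len(N), allowed),
                         orientation = config$edge_cap_orientations)
    if (length(ids) >= 3L) {
      model <- add_row(model, ids, rep(1, length(ids)), -Inf, 2,
                       sprintf("edge_neighbor_cap:%d", s))
    }
  }
  model
}

all_pairwise_overlap <- function(ivals) {
  for (a in 1:2) for (b in (a + 1):3) {
    if (min(ivals[[a]][2], ivals[[b]][2]) < max(ivals[[a]][1], ivals[[b]][1]))
      return(FALSE)
  }
  TRUE
}

allowed_partners <- function(s, N) unique(c(s - 1L, s + 1L, 1L, N))

#' Resolve the sequence neighbours of a strand
#'
#' Circular: the strand preceding the first is the last, the strand after
#' the last is the first. Strands shorter than `min_neighbor_length` are
#' stepped over (a very short strand cannot anchor a non-local contact);
#' if every other strand is short, the immediate circular neighbour is used.
#'
#' @param protein a `protein_record`.
#' @param s strand index.
#' @param config a `sheet_config`.
#' @return Integer vector `c(prev, next)` of resolved neighbour indices.
#' @export
resolved_neighbors <- function(protein, s, config = default_config()) {
  N <- n_strands(protein)
  L <- protein$strands$length
  step <- function(from, dir) {
    cur <- from
    for (t in seq_len(N - 1L)) {
      cur <- ((cur - 1L + dir) %% N) + 1L
      if (cur == s) break
      if (L[cur] >= config$min_neighbor_length) return(cur)
    }
    ((from - 1L + dir) %% N) + 1L   # fallback: immediate circular neighbour
  }
  c(prev = step(s, -1L), nxt = step(s, 1L))
}

#' Add the topological constraint family
#'
#' Non-local contact support (a non-local pair needs an active contact of
#' one of its members with a resolved sequence neighbour, with two extra
#' bridging terms at exactly the threshold separation); pretzel (crossing
#' quartet) exclusion; interlock requirement for non-local contacts;
#' terminal-strand sets pushing short, less hydrophobic strands to single
#' contacts.
#'
#' @param model a `topology_model`.
#' @param config a `sheet_config`.
#' @return The model with the rows appended.
#' @export
add_topological_constraints <- function(model, config = model$config) {
  N <- model$n_strands
  v <- model$vars
  thr <- config$nonlocal_threshold
  nb <- lapply(seq_len(N), function(s)
    resolved_neighbors(model$protein, s, config))

  # non-local support
  for (vi in y_idx(model)) {
    i <- v$i[vi]; j <- v$j[vi]
    if (j - i < thr) next
    support_pairs <- rbind(
      cbind(i, nb[[i]]), cbind(j, nb[[j]]))
    if (j - i == thr) {
      support_pairs <- rbind(support_pairs, c(i, j - 1L), c(i + 1L, j))
    }
    rhs <- integer(0)
    for (r in seq_len(nrow(support_pairs))) {
      a <- min(support_pairs[r, ]); b <- max(support_pairs[r, ])
      if (a == i && b == j) next
      if (a == b) next
      rhs <- c(rhs, pair_vars(model, a, b))
    }
    rhs <- unique(rhs)
    model <- add_row(model, c(vi, rhs), c(1, rep(-1, length(rhs))), -Inf, 0,
                     sprintf("nonlocal_support:%d-%d:%s", i, j, v$orientation[vi]))
  }

  # pretzel exclusion: for a quartet i<j<k<l forbid the two crossing chains
  if (N >= 4L) {
    quads <- utils::combn(N, 4L)
    for (qc in seq_len(ncol(quads))) {
      q <- quads[, qc]
      for (chain in list(rbind(q[c(1, 3)], q[c(1, 4)], q[c(2, 4)]),
                         rbind(q[c(1, 3)], q[c(2, 3)], q[c(2, 4)]))) {
        ids <- unlist(lapply(seq_len(3), function(r)
          pair_vars(model, chain[r, 1], chain[r, 2])))
        npres <- sum(vapply(seq_len(3), function(r)
          length(pair_vars(model, chain[r, 1], chain[r, 2])) > 0, logical(1)))
        if (npres == 3L) {
          model <- add_row(model, ids, rep(1, length(ids)), -Inf, 2,
                           sprintf("pretzel:%s", paste(q, collapse = "-")))
        }
      }
    }
  }

  # interlock: every non-local contact needs a bracketing non-local partner
  pairs <- unique(v[v$kind == "y", c("i", "j")])
  nonlocal <- pairs[pairs$j - pairs$i >= thr, , drop = FALSE]
  if (nrow(nonlocal)) {
    for (r in seq_len(nrow(nonlocal))) {
      i <- nonlocal$i[r]; k <- nonlocal$j[r]
      partners <- integer(0)
      for (r2 in seq_len(nrow(nonlocal))) {
        if (r2 == r) next
        jj <- nonlocal$i[r2]; ll <- nonlocal$j[r2]
        if ((i < jj && jj < k && k < ll) || (jj < i && i < ll && ll < k)) {
          partners <- c(partners, pair_vars(model, jj, ll))
        }
      }
      partners <- unique(partners)
      for (vi in pair_vars(model, i, k)) {
        model <- add_row(model, c(vi, partners),
                         c(1, rep(-1, length(partners))), -Inf, 0,
                         sprintf("interlock:%d-%d:%s", i, k, v$orientation[vi]))
      }
    }
  }

  # terminal sets: among the first 2k strands (sorted by length then
  # hydrophobic count, ascending) at least k have exactly one contact
  if (model$n_terminal_sets >= 1L) {
    for (s in model$vars$i[model$vars$kind == "z"]) {
      zid <- which(v$kind == "z" & v$i == s)
      deg <- incident_vars(model, s)
      model <- add_row(model, c(deg, zid), c(rep(1, length(deg)), 2),
                       -Inf, 3, sprintf("terminal_link:%d", s))
    }
    for (k in seq_len(model$n_terminal_sets)) {
      members <- model$terminal_order[seq_len(2L * k)]
      zids <- which(v$kind == "z" & v$i %in% members)
      model <- add_row(model, zids, rep(1, length(zids)), k, Inf,
                       sprintf("terminal_set:%d", k))
    }
  }
  model
}

#' Hydrogen-bond budget bounds for a protein
#'
#' The expected number of backbone hydrogen bonds contributed by strand
#' residues is `coeff * n_beta` (`coeff` defaults to 0.638); the admissible
#' integer window is the relative tolerance band around it, widened to the
#' nearest integer (with a warning) when rounding empties it.
#'
#' @param protein a `protein_record`.
#' @param config a `sheet_config`.
#' @return Integer vector `c(lo, hi)`.
#' @export
hbond_bounds <- function(protein, config = default_config()) {
  n_beta <- sum(protein$strands$length)
  target <- config$hbond_beta_coeff * n_beta
  lo <- ceiling((1 - config$hbond_tolerance) * target)
  hi <- floor((1 + config$hbond_tolerance) * target)
  if (lo > hi) {
    lo <- hi <- round(target)
    warning(sprintf(
      "hydrogen-bond window empty after rounding (target %.2f); using [%d, %d]",
      target, lo, hi))
  }
  c(lo = lo, hi = hi)
}

#' Add the hydrogen-bond budget constraint
#'
#' One realized residue pair counts as one hydrogen-bond unit; the total
#' over all active contacts must fall inside [hbond_bounds()].
#'
#' @param model a `topology_model`.
#' @param protein a `protein_record` (defaults to the model's).
#' @param config a `sheet_config`.
#' @return The model with the row appended.
#' @export
add_hbond_budget <- function(model, protein = model$protein,
                             config = model$config) {
  b <- hbond_bounds(protein, config)
  ids <- y_idx(model)
  add_row(model, ids, model$vars$npairs[ids], b[["lo"]], b[["hi"]],
          "hbond_budget")
}

# strand order used by the terminal sets: ascending length, then ascending
# hydrophobic residue count, then index (stable)
terminal_sort_order <- function(protein, config) {
  N <- n_strands(protein)
  hyd <- vapply(seq_len(N), function(s) hydrophobic_count(protein, s, config),
                numeric(1))
  order(protein$strands$length, hyd, seq_len(N))
}

#' Add an integer cut excluding one topology
#'
#' With `O` the strand-contact binaries active in `topology` (cardinality
#' `c`) and `Z` the inactive ones, appends `sum(O) - sum(Z) <= c - 1`.
#' Residue-level variables never enter cuts.
#'
#' @param model a `topology_model`.
#' @param topology the incumbent `sheet_topology` to exclude.
#' @return The model with the cut appended.
#' @export
add_integer_cut <- function(model, topology) {
  ids <- y_idx(model)
  active <- topology_var_ids(model, topology)
  coef <- ifelse(ids %in% active, 1, -1)
  add_row(model, ids, coef, -Inf, length(active) - 1,
          sprintf("integer_cut:%d", length(model$rows) + 1L))
}

# variable indices matching the (i, j, orientation) contacts of a topology
topology_var_ids <- function(model, topology) {
  unlist(lapply(topology$contacts, function(ct)
    pair_vars(model, ct$i, ct$j, ct$orientation)))
}

#' @export
print.topology_model <- function(x, ...) {
  cat(sprintf("<topology_model> %d strands, %d variables (%d contacts), %d rows\n",
              x$n_strands, nrow(x$vars), sum(x$vars$kind == "y"),
              length(x$rows)))
  invisible(x)
}
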