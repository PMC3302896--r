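#' Ranked topology prediction by iterated integer cuts
#'
#' Solves the topology model repeatedly. After each solve the incumbent is
#' screened: if its strand-contact graph contains a cycle (barrel-like
#' arrangement) or its contact-incompatibility graph is not two-colorable,
#' the solution is eliminated with a cut and the iteration does not consume
#' a rank; otherwise it is recorded, excluded with its integer cut, and the
#' search continues until `config$K` topologies are collected or the model
#' becomes infeasible.
#'
#' @param protein a `protein_record` with at least 3 strands.
#' @param scored_pairs output of [score_all_pairs()].
#' @param config a `sheet_config`; `K`, the solver time limit and all model
#'   parameters are taken from it.
#' @param verbose emit one log line per iteration (iteration, objective,
#'   outcome: rank / cycle cut / coloring cut).
#' @return A list of `sheet_topology` objects, ranks 1..K, objectives
#'   non-increasing. Attribute `partial` is `TRUE` when the solver hit its
#'   time limit before the list was complete.
#' @export
solve_ranked <- function(protein, scored_pairs, config = default_config(),
                         verbose = FALSE) {
  model <- build_model(protein, scored_pairs, config)
  solve_ranked_model(model, config, verbose = verbose)
}

# the iteration loop, exposed separately so a caller can pre-build or
# modify the model
solve_ranked_model <- function(model, config = model$config, verbose = FALSE) {
  out <- list()
  iter <- 0L
  max_iter <- 50L + 40L * config$K
  partial <- FALSE
  t0 <- Sys.time()
  while (length(out) < config$K && iter < max_iter) {
    iter <- iter + 1L
    budget <- config$solver_time_limit -
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (budget <= 0) { partial <- TRUE; break }
    sol <- solve_binary_program(model$obj, model$rows, time_limit = budget,
                                cap = model$n_strands - 1L,
                                cap_mask = model$vars$kind == "y")
    if (sol$status == "timeout") { partial <- TRUE; break }
    if (sol$status == "infeasible") break
    topo <- topology_from_solution(model, sol)
    cycles <- find_cycles(topo)
    if (length(cycles)) {
      for (cyc in cycles) model <- add_subtour_cut(model, cyc)
      if (verbose) message(sprintf("iter %d: objective %.4f -> cycle cut (%d)",
                                   iter, sol$objective, length(cycles)))
      next
    }
    col <- is_two_colorable(topo)
    if (!col$ok) {
      model <- add_coloring_cut(model, topo, col$witness)
      if (verbose) message(sprintf("iter %d: objective %.4f -> coloring cut",
                                   iter, sol$objective))
      next
    }
    topo$rank <- length(out) + 1L
    out[[topo$rank]] <- topo
    model <- add_integer_cut(model, topo)
    if (verbose) message(sprintf("iter %d: objective %.4f -> rank %d",
                                 iter, sol$objective, topo$rank))
  }
  attr(out, "partial") <- partial
  attr(out, "iterations") <- iter
  out
}

# read a solver solution back into a sheet_topology; residue pairs come
# from the stored best alignments (the equality linking of the residue
# variables makes them fully determined by the strand binaries)
topology_from_solution <- function(model, sol) {
  active <- which(sol$x == 1L & model$vars$kind == "y")
  contacts <- lapply(active, function(vi) {
    al <- model$alignments[[vi]]
    strand_contact(al$i, al$j, al$orientation, al$offset, al$pairs)
  })
  sheet_topology(contacts, objective = sol$objective,
                 n_strands = model$n_strands)
}

# subtour cut: a cycle of strands cannot keep all its edges
add_subtour_cut <- function(model, cycle) {
  k <- length(cycle)
  ids <- unlist(lapply(seq_len(k), function(r) {
    a <- cycle[r]; b <- cycle[if (r == k) 1L else r + 1L]
    pair_vars(model, a, b)
  }))
  add_row(model, ids, rep(1, length(ids)), -Inf, k - 1,
          sprintf("subtour:%s", paste(cycle, collapse = "-")))
}

# coloring cut: the oriented contacts of an odd incompatibility cycle can
# never all be active together
add_coloring_cut <- function(model, topology, witness) {
  ids <- unlist(lapply(topology$contacts[witness], function(ct)
    pair_vars(model, ct$i, ct$j, ct$orientation)))
  add_row(model, ids, rep(1, length(ids)), -Inf, length(witness) - 1,
          sprintf("coloring:%s", paste(witness, collapse = "-")))
}

#' End-to-end topology prediction
#'
#' Convenience wrapper: filters short strands, scores all pairs and runs the
#' ranked solve.
#'
#' @param protein a `protein_record` with strands attached.
#' @param table residue-pair potential matrix (default
#'   [default_potential()]).
#' @param config a `sheet_config`.
#' @param verbose passed to [solve_ranked()].
#' @return A ranked list of `sheet_topology` objects.
#' @export
predict_topologies <- function(protein, table = default_potential(),
                               config = default_config(), verbose = FALSE) {
  protein <- filter_short_strands(protein, config$min_strand_length)
  sp <- score_all_pairs(protein, table, config)
  solve_ranked(protein, sp, config, verbose = verbose)
}
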