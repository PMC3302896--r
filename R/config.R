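#' Default model configuration
#'
#' Returns the full set of tunable parameters for strand-pair scoring, the
#' topology optimization model and the ranked-solution loop. Every parameter
#' can be overridden by name through `...` or by editing the returned list.
#'
#' @details
#' The main knobs are:
#' \describe{
#'   \item{`min_overlap`}{Minimum number of aligned residue pairs for a
#'     strand-pair alignment to be considered at all (default 2).}
#'   \item{`locality_weights`}{Multiplicative correction applied to raw pair
#'     scores by strand separation `d = j - i`: element `d` of the vector is
#'     used, with the last element reused for all larger separations. The
#'     default `c(0.9, 1.0)` down-weights nearest-neighbour (local) contacts,
#'     countering the local bias of database-derived potentials.}
#'   \item{`max_contacts_per_strand`}{Cap on the number of strands any one
#'     strand may pair with (default 3; strands are two-faced, but a long
#'     strand can host two short partners on one face).}
#'   \item{`budget_lo_slack`, `budget_lo_min`, `budget_hi_factor`}{Residue
#'     budget rules per strand of length L: the total number of partner
#'     residues aligned against the strand must lie in
#'     `[max(budget_lo_min, L - budget_lo_slack), budget_hi_factor * L]`.}
#'   \item{`nonlocal_threshold`}{Minimum index separation `j - i` for a
#'     contact to count as non-local (default 3).}
#'   \item{`min_neighbor_length`}{Strands shorter than this are skipped when
#'     resolving sequence neighbours for the non-local support rule
#'     (default 4, i.e. strands of length 2-3 are stepped over).}
#'   \item{`hbond_beta_coeff`, `hbond_tolerance`}{The expected number of
#'     backbone hydrogen bonds in strand regions is
#'     `hbond_beta_coeff * (number of strand residues)`; the realized number
#'     of residue contacts must fall within `hbond_tolerance` (relative)
#'     of that value. Defaults 0.638 and 0.15.}
#'   \item{`hydrophobic_set`}{One-letter codes counted as hydrophobic when
#'     ranking strands for the terminal-strand sets.}
#'   \item{`terminal_set_stride`}{One terminal-strand set is imposed for
#'     every this many strands in the protein (default 5).}
#'   \item{`K`}{Number of ranked topologies requested (default 25).}
#'   \item{`min_strand_length`}{Strands shorter than this are merged back
#'     into coil before modelling (default 2).}
#'   \item{`restraint_window`}{Lower/upper N--O distance bounds in Angstrom
#'     used when exporting hydrogen-bond distance restraints.}
#' }
#'
#' @param ... named overrides of any default parameter.
#' @return A named list of class `sheet_config`.
#' @examples
#' cfg <- default_config(K = 5, hbond_tolerance = 0.2)
#' cfg$K
#' @export
default_config <- function(...) {
  cfg <- list(
    min_overlap              = 2L,
    locality_weights         = c(0.9, 1.0),
    locality_weights_parallel = NULL,   # NULL = share locality_weights
    max_contacts_per_strand  = 3L,
    budget_lo_slack          = 2L,
    budget_lo_min            = 1L,
    budget_hi_factor         = 2,
    nonlocal_threshold       = 3L,
    min_neighbor_length      = 4L,
    edge_cap_orientations    = c("A", "P"),
    hbond_beta_coeff         = 0.638,
    hbond_tolerance          = 0.15,
    hydrophobic_set          = c("A", "V", "L", "I", "M", "F", "W", "C", "Y"),
    terminal_set_stride      = 5L,
    K                        = 25L,
    min_strand_length        = 2L,
    strict_residue_sharing   = FALSE,
    solver_time_limit        = Inf,
    solver_gap               = 0,
    random_seed              = 1L,
    restraint_window         = c(2.7, 3.3)
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  class(cfg) <- c("sheet_config", "list")
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    all(cfg$locality_weights > 0),
    cfg$hbond_tolerance > 0, cfg$hbond_tolerance < 1,
    cfg$K >= 1,
    cfg$min_overlap >= 1,
    cfg$max_contacts_per_strand >= 1,
    cfg$budget_hi_factor > 0,
    cfg$nonlocal_threshold >= 2,
    cfg$terminal_set_stride >= 1
  )
  invisible(cfg)
}

#' Read a model configuration from a YAML or JSON file
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file whose top level is a
#'   mapping of parameter names to values.
#' @return A `sheet_config` list (defaults overridden by the file).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  do.call(default_config, raw)
}

#' @export
print.sheet_config <- function(x, ...) {
  cat("<sheet_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm, paste(format(val), collapse = " ")))
  }
  invisible(x)
}

# locality weight for a strand separation d >= 1 (last element extends)
locality_weight <- function(cfg, d, orientation = "A") {
  w <- cfg$locality_weights
  if (orientation == "P" && !is.null(cfg$locality_weights_parallel)) {
    w <- cfg$locality_weights_parallel
  }
  w[min(d, length(w))]
}
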