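#' Solve a binary linear maximization problem
#'
#' A small exact depth-first branch-and-bound solver for pure 0/1 linear
#' programs with two-sided row bounds, written for the modest model sizes
#' this package produces (tens of binaries). It prunes on row activity
#' intervals, propagates forced assignments to a fixpoint, and bounds the
#' objective by the sum of positive free coefficients. The search order is
#' fixed (variables by decreasing absolute objective coefficient, promising
#' branch first), so the reported optimum is deterministic; among exactly
#' tied optima the first one encountered is returned. The search core is
#' implemented in C++.
#'
#' @param obj numeric objective coefficients (one per variable).
#' @param rows list of constraints, each `list(idx, coef, lo, hi)` meaning
#'   `lo <= sum(coef * x[idx]) <= hi` (use `-Inf`/`Inf` for one-sided rows).
#' @param time_limit wall-clock seconds before the search aborts with status
#'   `"timeout"` (best incumbent, if any, is still returned).
#' @param cap optional cardinality cap used to strengthen the objective
#'   bound: at most `cap` of the variables flagged in `cap_mask` can be 1
#'   (must also be stated as a row to constrain the solution itself).
#' @param cap_mask logical vector flagging the capped variables.
#' @return A list with `status` (`"optimal"`, `"infeasible"` or
#'   `"timeout"`), `x` (0/1 vector), `objective` and `nodes` (search nodes
#'   explored).
#' @export
solve_binary_program <- function(obj, rows, time_limit = Inf,
                                 cap = -1L, cap_mask = logical(0)) {
  .bnb_solve(as.numeric(obj), rows, as.numeric(time_limit),
             as.integer(cap), as.logical(cap_mask))
}
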