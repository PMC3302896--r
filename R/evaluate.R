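#' Strand-pair confusion counts
#'
#' Compares a predicted and a native topology over the universe of all
#' `C(N, 2)` unordered strand pairs. In the default `"pair"` mode a
#' predicted contact counts as a true positive whenever the native topology
#' pairs the same strands, regardless of orientation; in
#' `"pair_orientation"` mode a right-pair/wrong-orientation prediction is
#' counted as both a false positive and a false negative (so the four
#' counts then sum to `C(N, 2)` plus the number of orientation mismatches).
#'
#' @param predicted,native `sheet_topology` objects (or plain data frames
#'   with columns `i`, `j` and optionally `orientation`) over the same
#'   strand index set.
#' @param n_strands number of strands N; defaults to the larger
#'   `n_strands` of the two topologies.
#' @param mode `"pair"` (default) or `"pair_orientation"`.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(predicted, native, n_strands = NULL,
                      mode = c("pair", "pair_orientation")) {
  mode <- match.arg(mode)
  p <- contact_df(predicted); v <- contact_df(native)
  if (is.null(n_strands)) {
    n_strands <- max(topo_n(predicted), topo_n(native))
  }
  if (max(c(0L, p$i, p$j, v$i, v$j)) > n_strands) {
    stop("contact indices exceed n_strands; map strand sets first (map_strands)")
  }
  total <- choose(n_strands, 2)
  pk <- paste(p$i, p$j); vk <- paste(v$i, v$j)
  if (mode == "pair") {
    tp <- length(intersect(pk, vk))
    fp <- length(setdiff(pk, vk))
    fn <- length(setdiff(vk, pk))
    tn <- total - tp - fp - fn
  } else {
    pko <- paste(pk, p$orientation); vko <- paste(vk, v$orientation)
    tp <- length(intersect(pko, vko))
    fp <- nrow(p) - tp
    fn <- nrow(v) - tp
    tn <- total - length(union(pk, vk))
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

contact_df <- function(x) {
  if (inherits(x, "sheet_topology")) {
    e <- contact_edges(x)
    data.frame(i = e[, 1], j = e[, 2],
               orientation = contact_orientations(x))
  } else {
    df <- as.data.frame(x)
    ii <- pmin(df$i, df$j); jj <- pmax(df$i, df$j)
    data.frame(i = ii, j = jj,
               orientation = if ("orientation" %in% names(df))
                 df$orientation else rep(NA_character_, nrow(df)))
  }
}

topo_n <- function(x) {
  if (inherits(x, "sheet_topology")) x$n_strands
  else max(c(0L, x$i, x$j))
}

#' Precision, recall and Matthews correlation from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `mcc = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#' Zero denominators follow a fixed convention: precision and recall are 0
#' when their denominator is 0, MCC is 0 when any factor under the root is
#' 0; applied conventions are flagged in the `"flags"` attribute.
#'
#' @param conf a `confusion_counts` object (or list with tp/fp/tn/fn).
#' @return A list of class `sheet_metrics` with `precision`, `recall`,
#'   `mcc`.
#' @export
metrics <- function(conf) {
  tp <- conf$tp; fp <- conf$fp; tn <- conf$tn; fn <- conf$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  flags <- character(0)
  if (tp + fp == 0) { precision <- 0; flags <- c(flags, "precision: tp+fp=0") }
  else precision <- tp / (tp + fp)
  if (tp + fn == 0) { recall <- 0; flags <- c(flags, "recall: tp+fn=0") }
  else recall <- tp / (tp + fn)
  denom <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (denom == 0) { mcc <- 0; flags <- c(flags, "mcc: zero factor") }
  else mcc <- (tp * tn - fp * fn) / sqrt(denom)
  structure(list(precision = precision, recall = recall, mcc = mcc),
            class = "sheet_metrics", flags = flags)
}

#' @export
print.sheet_metrics <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  mcc %.4f\n",
              x$precision, x$recall, x$mcc))
  fl <- attr(x, "flags")
  if (length(fl)) cat("  conventions:", paste(fl, collapse = "; "), "\n")
  invisible(x)
}

#' Weighted average of per-protein metrics over strand-count bins
#'
#' Proteins are binned by strand count; the summary is
#' `sum_s(mean_s * count_s) / sum_s(count_s)` per metric, i.e. the bin
#' means weighted by bin occupancy (which equals the plain per-protein mean).
#'
#' @param per_protein data frame with a `n_strands` column and one or more
#'   numeric metric columns (e.g. `precision`, `recall`, `mcc`).
#' @return Named numeric vector of weighted averages, one per metric column.
#' @export
weighted_average <- function(per_protein) {
  if (!nrow(per_protein)) stop("no per-protein metrics supplied")
  stopifnot("n_strands" %in% names(per_protein))
  metric_cols <- setdiff(names(per_protein)[vapply(per_protein, is.numeric,
                                                   logical(1))], "n_strands")
  counts <- table(per_protein$n_strands)
  vapply(metric_cols, function(mc) {
    avg_s <- tapply(per_protein[[mc]], per_protein$n_strands, mean)
    sum(avg_s * as.numeric(counts[names(avg_s)])) / sum(counts)
  }, numeric(1))
}

#' Best metrics among the top k ranked topologies
#'
#' Evaluates ranks 1..k against the native topology and returns the metrics
#' of the best one: highest MCC, ties broken by precision, then by lower
#' rank.
#'
#' @param ranked_topologies ranked list of `sheet_topology`.
#' @param native the native `sheet_topology`.
#' @param k number of top solutions to consider (`k <=` list length).
#' @param mode confusion mode, see [confusion()].
#' @return A `sheet_metrics` object with attribute `rank` (the winning
#'   rank).
#' @export
best_of_top_k <- function(ranked_topologies, native, k = length(ranked_topologies),
                          mode = "pair") {
  stopifnot(k >= 1, k <= length(ranked_topologies))
  best <- NULL; best_rank <- NA_integer_
  for (r in seq_len(k)) {
    m <- metrics(confusion(ranked_topologies[[r]], native, mode = mode))
    if (is.null(best) || m$mcc > best$mcc + 1e-12 ||
        (abs(m$mcc - best$mcc) <= 1e-12 && m$precision > best$precision + 1e-12)) {
      best <- m; best_rank <- r
    }
  }
  attr(best, "rank") <- best_rank
  best
}

#' Map predicted strands onto native strands
#'
#' Greedy maximum-residue-overlap matching, one-to-one; a mapping requires
#' at least one shared residue. Strands without a partner are left unmapped
#' and should be excluded from evaluation.
#'
#' @param predicted_strands,native_strands strand tables (data frames with
#'   `start`, `end`; `index` is derived from row order if absent) over the
#'   same sequence.
#' @return Data frame with columns `predicted`, `native`, `overlap`.
#' @export
map_strands <- function(predicted_strands, native_strands) {
  ps <- as.data.frame(predicted_strands); ns <- as.data.frame(native_strands)
  if (!"index" %in% names(ps)) ps$index <- seq_len(nrow(ps))
  if (!"index" %in% names(ns)) ns$index <- seq_len(nrow(ns))
  ov <- outer(seq_len(nrow(ps)), seq_len(nrow(ns)),
              Vectorize(function(a, b) {
                max(0L, min(ps$end[a], ns$end[b]) -
                      max(ps$start[a], ns$start[b]) + 1L)
              }))
  out <- data.frame(predicted = integer(), native = integer(),
                    overlap = integer())
  while (any(ov >= 1L)) {
    hit <- which(ov == max(ov), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    out <- rbind(out, data.frame(predicted = ps$index[hit[1]],
                                 native = ns$index[hit[2]],
                                 overlap = ov[hit[1], hit[2]]))
    ov[hit[1], ] <- 0L; ov[, hit[2]] <- 0L
  }
  out[order(out$predicted), , drop = FALSE]
}

#' Residue-level accuracy over correctly predicted strand pairs
#'
#' Restricted to strand pairs present in both topologies (orientation
#' ignored), the fraction of predicted residue pairs that exactly match a
#' native residue pair.
#'
#' @param predicted_topology,native_topology `sheet_topology` objects over
#'   the same strand set.
#' @return Fraction in [0, 1], or `NA` (with attribute `reason`) when no
#'   strand pair is correctly predicted.
#' @export
aligned_pair_accuracy <- function(predicted_topology, native_topology) {
  pk <- paste(contact_df(predicted_topology)$i, contact_df(predicted_topology)$j)
  vk <- paste(contact_df(native_topology)$i, contact_df(native_topology)$j)
  common <- intersect(pk, vk)
  if (!length(common)) {
    return(structure(NA_real_, reason = "no correctly predicted strand pairs"))
  }
  native_pairs <- unlist(lapply(native_topology$contacts, function(ct) {
    if (paste(ct$i, ct$j) %in% common)
      paste(ct$residue_pairs[, 1], ct$residue_pairs[, 2])
  }))
  pred_pairs <- unlist(lapply(predicted_topology$contacts, function(ct) {
    if (paste(ct$i, ct$j) %in% common)
      paste(ct$residue_pairs[, 1], ct$residue_pairs[, 2])
  }))
  mean(pred_pairs %in% native_pairs)
}
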