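#' Residue-pair contact potentials
#'
#' The optimization layer is agnostic to where pair scores come from: any
#' symmetric 20x20 table over the standard one-letter codes can be supplied.
#' [default_potential()] ships a simple, documented hydrophobicity-product
#' propensity: buried beta-sheet cores are enriched in hydrophobic-hydrophobic
#' cross-strand neighbours, so the score of a residue pair is the scaled sum
#' of the Kyte-Doolittle hydropathies of its members. It is a deliberately
#' transparent stand-in for trained pairwise potentials and is expected to be
#' replaced by the user for serious prediction work.
#'
#' Residues coded `X` (any non-standard residue) score 0 against everything,
#' whatever the table says.
#'
#' @return A symmetric 20x20 numeric matrix with dimnames, attribute
#'   `name` recording provenance.
#' @examples
#' pot <- default_potential()
#' pot["V", "I"]  # favourable (both hydrophobic)
#' pot["D", "E"]  # unfavourable
#' @export
default_potential <- function() {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  kd <- kd[STANDARD_AA] / 4.5            # scale to [-1, 1]
  m <- outer(kd, kd, function(a, b) round((a + b) / 2, 4))
  dimnames(m) <- list(STANDARD_AA, STANDARD_AA)
  attr(m, "name") <- "kyte-doolittle-sum default"
  m
}

#' Read a residue-pair potential table from TSV
#'
#' Expected layout: a header row of one-letter codes, then one row per code
#' (`code<TAB>20 numbers`). The table must be symmetric over the 20 standard
#' residues and contain only finite values.
#'
#' @param path path to the TSV file.
#' @return A symmetric 20x20 numeric matrix with attribute `name` set to the
#'   file name.
#' @export
read_potential_table <- function(path) {
  if (!file.exists(path)) stop("potential table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  missing <- setdiff(STANDARD_AA, rownames(m))
  if (length(missing) || !setequal(colnames(m), rownames(m))) {
    stop("potential table must cover the 20 standard residues; missing: ",
         paste(missing, collapse = " "))
  }
  m <- m[STANDARD_AA, STANDARD_AA]
  if (any(!is.finite(m))) stop("potential table contains non-finite entries")
  if (max(abs(m - t(m))) > 1e-8) stop("potential table is not symmetric")
  storage.mode(m) <- "double"
  attr(m, "name") <- basename(path)
  m
}

#' Write a potential table as TSV
#'
#' @param table symmetric 20x20 matrix as returned by [default_potential()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_potential_table <- function(table, path) {
  df <- as.data.frame(table[STANDARD_AA, STANDARD_AA])
  utils::write.table(cbind(data.frame(aa = STANDARD_AA), df), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# vectorized score lookup; X (or anything absent from the table) scores 0
pot_lookup <- function(table, a, b) {
  ok <- a %in% rownames(table) & b %in% colnames(table)
  out <- numeric(length(a))
  if (any(ok)) out[ok] <- table[cbind(a[ok], b[ok])]
  out
}
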