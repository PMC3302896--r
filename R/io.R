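#' Read a protein sequence from a FASTA file
#'
#' The first record is used unless `which` selects another. The sequence is
#' uppercased, whitespace-stripped and non-standard residues are mapped to
#' `X`.
#'
#' @param path path to a FASTA file.
#' @param which record index to use (default 1).
#' @return A `protein_record` with sequence only (no strands).
#' @export
read_fasta <- function(path, which = 1L) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  seq_lines <- !startsWith(raw, ">")
  bad <- which(seq_lines & grepl("[^A-Za-z*.[:space:]-]", raw))
  if (length(bad)) {
    stop(sprintf("FASTA format error in %s: illegal character on line %d: %s",
                 path, bad[1], raw[bad[1]]))
  }
  set <- tryCatch(suppressWarnings(Biostrings::readAAStringSet(path)),
                  error = function(e) stop("FASTA format error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  if (which > length(set)) stop("record ", which, " requested but file has ",
                                length(set), " record(s)")
  id <- strsplit(names(set)[which], "[[:space:]]+")[[1]][1]
  protein_record(id = id, sequence = as.character(set[[which]]))
}

#' Read a strand table and attach it to a protein
#'
#' Plain-text stand-in for a DSSP assignment: a 3-column TSV
#' (`strand_id`, `start`, `end`), coordinates 1-based inclusive. Strand
#' indices are re-derived from sequence order regardless of the ids in the
#' file.
#'
#' @param path path to the TSV (a header line is detected and skipped).
#' @param protein a `protein_record` carrying the sequence.
#' @return The `protein_record` with strands attached and `f_beta` computed.
#' @export
read_strand_table <- function(path, protein) {
  if (!file.exists(path)) stop("strand table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("strand table is empty: ", path)
  fields <- strsplit(lines, "[\t ]+")
  if (suppressWarnings(is.na(as.integer(fields[[1]][2])))) fields <- fields[-1]
  rows <- lapply(seq_along(fields), function(r) {
    f <- fields[[r]]
    if (length(f) < 3L) stop("strand table line ", r, " has fewer than 3 columns")
    se <- suppressWarnings(as.integer(f[2:3]))
    if (anyNA(se)) stop("non-integer coordinates on strand table line ", r)
    se
  })
  st <- data.frame(start = vapply(rows, `[`, integer(1), 1),
                   end = vapply(rows, `[`, integer(1), 2))
  attach_strands(protein, st)
}

#' Parse a DSSP output file
#'
#' Reads a standard (v2-style, fixed-column) DSSP file: residues with
#' structure code `E` are grouped into maximal runs and become strands;
#' `H`, `G`, `I` runs become helix segments. Residue numbering follows the
#' order of data lines (1-based), chain breaks (`!`) are skipped.
#'
#' @param path path to the DSSP file.
#' @param id identifier for the returned record (default: file name).
#' @return A `protein_record` with strands, helix segments and secondary
#'   structure fractions.
#' @export
read_dssp <- function(path, id = NULL) {
  if (!file.exists(path)) stop("DSSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP file (missing '  #  RESIDUE' header): ", path)
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nzchar(body)]
  aa <- character(0); ss <- character(0)
  for (ln in seq_along(body)) {
    l <- body[ln]
    if (nchar(l) < 17L) {
      stop("unparseable DSSP record at line ", hdr[1] + ln, " of ", path)
    }
    res <- substr(l, 14, 14)
    if (res == "!") next   # chain break
    aa <- c(aa, res)
    ss <- c(ss, substr(l, 17, 17))
  }
  if (!length(aa)) stop("DSSP file has no residue records: ", path)
  seq <- paste(aa, collapse = "")
  runs_of <- function(codes) {
    inset <- ss %in% codes
    r <- rle(inset)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    data.frame(start = starts[r$values], end = ends[r$values])
  }
  helices <- runs_of(c("H", "G", "I"))
  strands <- runs_of("E")
  protein_record(id = if (is.null(id)) basename(path) else id,
                 sequence = seq, strands = strands,
                 helix_segments = if (nrow(helices)) helices else NULL)
}

#' Write ranked topologies to a JSON report
#'
#' @param topologies list of `sheet_topology` objects (non-empty).
#' @param path output path.
#' @param id protein identifier recorded in the report.
#' @param config_hash optional configuration digest string.
#' @return `path`, invisibly.
#' @export
write_topologies <- function(topologies, path, id = "", config_hash = "") {
  if (!length(topologies)) stop("empty topology list")
  report <- list(
    id = id, config_hash = config_hash,
    topologies = lapply(topologies, function(tp) {
      list(rank = tp$rank, objective = tp$objective,
           n_strands = tp$n_strands,
           contacts = lapply(tp$contacts, function(ct) {
             list(i = ct$i, j = ct$j, orientation = ct$orientation,
                  offset = ct$offset,
                  residue_pairs = unname(apply(ct$residue_pairs, 1, as.list)))
           }),
           sheets = unname(tp$sheets))
    }))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a topology report written by [write_topologies()]
#'
#' Also accepts the same schema for hand-written native topologies.
#'
#' @param path path to the JSON report.
#' @return A list with `id`, `config_hash` and `topologies` (list of
#'   `sheet_topology`).
#' @export
read_topologies <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  topologies <- lapply(raw$topologies, function(tp) {
    contacts <- lapply(tp$contacts, function(ct) {
      rp <- do.call(rbind, lapply(ct$residue_pairs, function(p) {
        c(p[[1]], p[[2]])
      }))
      strand_contact(ct$i, ct$j, ct$orientation, ct$offset, rp)
    })
    sheet_topology(contacts,
                   objective = if (is.null(tp$objective)) NA_real_ else tp$objective,
                   rank = if (is.null(tp$rank)) NA_integer_ else tp$rank,
                   n_strands = tp$n_strands)
  })
  list(id = raw$id, config_hash = raw$config_hash, topologies = topologies)
}

#' Export hydrogen-bond distance restraints for a topology
#'
#' Each predicted residue pair becomes one TSV row
#' `(res_k, res_l, lower_A, upper_A)` with the configured N--O distance
#' window, suitable as input to a torsion-angle-dynamics or
#' distance-geometry stage.
#'
#' @param topology a `sheet_topology`.
#' @param path output TSV path.
#' @param window numeric length-2 lower/upper bound in Angstrom.
#' @return `path`, invisibly.
#' @export
export_restraints <- function(topology, path,
                              window = default_config()$restraint_window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  rows <- do.call(rbind, lapply(topology$contacts, function(ct) ct$residue_pairs))
  if (is.null(rows)) rows <- matrix(integer(), ncol = 2)
  df <- data.frame(res_k = rows[, 1], res_l = rows[, 2],
                   lower_A = rep(window[1], nrow(rows)),
                   upper_A = rep(window[2], nrow(rows)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
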