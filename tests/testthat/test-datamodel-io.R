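test_that("FASTA reading normalizes sequences and rejects bad input", {
  tf <- withr::local_tempfile(lines = c(">p", "VIVIV"))
  rec <- read_fasta(tf)
  expect_equal(rec$sequence, "VIVIV")
  expect_equal(rec$n_residues, 5L)
  expect_equal(rec$id, "p")

  tf2 <- withr::local_tempfile(lines = c(">p desc here", "vi vi", "v"))
  expect_equal(read_fasta(tf2)$sequence, "VIVIV")

  tf3 <- withr::local_tempfile(lines = character(0))
  expect_error(read_fasta(tf3), "no records")

  tf4 <- withr::local_tempfile(lines = c(">p", "VI1IV"))
  expect_error(read_fasta(tf4), "line 2")

  # non-standard residues map to X and score 0 everywhere
  tf5 <- withr::local_tempfile(lines = c(">p", "VBUZV"))
  expect_equal(read_fasta(tf5)$sequence, "VXXXV")
})

test_that("strand tables attach, re-sort and validate against the sequence", {
  p <- protein_record("p", "VIVIVIVIV")   # 9-mer
  tf <- withr::local_tempfile(lines = c("strand_id\tstart\tend",
                                        "1\t1\t3", "2\t5\t7"))
  rec <- read_strand_table(tf, p)
  expect_equal(nrow(rec$strands), 2L)
  expect_equal(rec$strands$length, c(3L, 3L))
  expect_equal(rec$f_beta, 6 / 9)
  expect_equal(rec$strands$residues, c("VIV", "VIV"))

  # out-of-order rows are re-sorted and re-indexed by position
  tf2 <- withr::local_tempfile(lines = c("2\t5\t7", "1\t1\t3"))
  rec2 <- read_strand_table(tf2, p)
  expect_equal(rec2$strands$start, c(1L, 5L))
  expect_equal(rec2$strands$index, c(1L, 2L))

  tf3 <- withr::local_tempfile(lines = c("1\t1\t3", "2\t3\t5"))
  expect_error(read_strand_table(tf3, p), "overlap")

  tf4 <- withr::local_tempfile(lines = c("1\t1\t30"))
  expect_error(read_strand_table(tf4, p), "outside")
})

test_that("DSSP parsing groups E runs into strands and computes fractions", {
  seq <- "AVIVAGAVLVAG"
  ss  <- "  EEE  EEE  "
  tf <- withr::local_tempfile(lines = make_dssp_text(seq, ss))
  rec <- read_dssp(tf)
  expect_equal(nrow(rec$strands), 2L)
  expect_equal(rec$strands$length, c(3L, 3L))
  expect_equal(rec$strands$start, c(3L, 8L))
  expect_equal(rec$sequence, seq)
  # parser totals: strand residues equal the number of E codes
  expect_equal(sum(rec$strands$length),
               sum(strsplit(ss, "")[[1]] == "E"))

  # helices populate f_alpha
  tf2 <- withr::local_tempfile(
    lines = make_dssp_text("AVIVAGAVLVAG", " HHHH   EEE "))
  rec2 <- read_dssp(tf2)
  expect_equal(rec2$f_alpha, 4 / 12)
  expect_equal(rec2$f_beta, 3 / 12)

  # all-coil: zero strands, and prediction refuses downstream
  tf3 <- withr::local_tempfile(lines = make_dssp_text("AVIVA", "     "))
  rec3 <- read_dssp(tf3)
  expect_equal(nrow(rec3$strands), 0L)
  expect_error(score_all_pairs(rec3, uniform_table()), "at least 3 strands")

  # length-1 E runs are kept by the parser (filtering is a config concern)
  tf4 <- withr::local_tempfile(lines = make_dssp_text("AVIVA", " E E "))
  expect_equal(read_dssp(tf4)$strands$length, c(1L, 1L))

  tf5 <- withr::local_tempfile(lines = c("not a dssp file", "at all"))
  expect_error(read_dssp(tf5), "DSSP")
})

test_that("topology JSON round-trips and restraints export one row per pair", {
  p <- toy_protein(c("VIVIV", "IVIVI", "VIVIV"))
  sp <- score_all_pairs(p, uniform_table(), default_config())
  a12 <- sp_get(sp, 1, 2, "A"); a23 <- sp_get(sp, 2, 3, "A")
  topo <- sheet_topology(list(
    strand_contact(1, 2, "A", a12$offset, a12$pairs),
    strand_contact(2, 3, "A", a23$offset, a23$pairs)),
    objective = a12$corrected_score + a23$corrected_score,
    rank = 1L, n_strands = 3L)

  tf <- withr::local_tempfile(fileext = ".json")
  write_topologies(list(topo), tf, id = "toy")
  back <- read_topologies(tf)
  expect_equal(back$id, "toy")
  rt <- back$topologies[[1]]
  expect_equal(rt$rank, 1L)
  expect_equal(rt$objective, topo$objective)
  expect_equal(length(rt$contacts), 2L)
  expect_equal(rt$contacts[[1]]$residue_pairs, topo$contacts[[1]]$residue_pairs)
  expect_equal(rt$sheets, topo$sheets)

  expect_error(write_topologies(list(), tf), "empty")

  rf <- withr::local_tempfile(fileext = ".tsv")
  export_restraints(topo, rf, window = c(2.7, 3.3))
  df <- read.delim(rf)
  expect_equal(nrow(df), nrow(a12$pairs) + nrow(a23$pairs))
  expect_true(all(df$lower_A == 2.7 & df$upper_A == 3.3))
})

test_that("protein record invariants hold", {
  p <- protein_record("p", "VIVIVIVIV",
                      strands = data.frame(start = c(1, 5), end = c(3, 7)))
  expect_equal(p$strands$length, p$strands$end - p$strands$start + 1L)
  expect_equal(p$f_beta, sum(p$strands$length) / p$n_residues)
  expect_error(protein_record("p", ""), "empty")
  expect_error(protein_record("p", "VIV",
                              strands = data.frame(start = 3, end = 1)))
  # filter_short_strands merges short strands into coil and re-indexes
  p2 <- protein_record("p", "VIVIVIVIV",
                       strands = data.frame(start = c(1, 5, 8),
                                            end = c(3, 5, 9)))
  f <- filter_short_strands(p2, 2L)
  expect_equal(f$strands$start, c(1L, 8L))
  expect_equal(f$strands$index, c(1L, 2L))
})
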