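test_that("align_pair matches hand-checked registers", {
  cfg <- default_config()
  # identical V-V strands, parallel, unit scores: full overlap at offset 0
  p <- toy_protein(c("VV", "VV", "VV"))
  al <- align_pair(p$strands[1, ], p$strands[2, ], "P", uniform_table(1), cfg)
  expect_equal(al$offset, 0L)
  expect_equal(al$raw_score, 2)
  expect_equal(al$overlap_i, 2L)

  # AV vs VA antiparallel under V-V=2, A-A=2, A-V=0: frozen against the
  # exhaustive-offset oracle (offset 0 aligns A-A and V-V, score 4)
  tab <- pair_table(list("V", "V", 2), list("A", "A", 2))
  p2 <- toy_protein(c("AV", "VA", "AA"))
  al2 <- align_pair(p2$strands[1, ], p2$strands[2, ], "A", tab, cfg)
  orc <- oracle_best_alignment(c("A", "V"), c("V", "A"), "A", tab)
  expect_equal(al2$raw_score, 4)
  expect_equal(orc$score, 4)
  expect_equal(al2$offset, orc$offset)

  # too short for min_overlap: no valid alignment
  p3 <- toy_protein(c("V", "VV", "VV"))
  expect_null(align_pair(p3$strands[1, ], p3$strands[2, ], "P",
                         uniform_table(1), cfg))
})

test_that("align_pair equals the exhaustive-offset oracle on random strands", {
  cfg <- default_config()
  aa <- rownames(default_potential())
  set.seed(42)
  for (trial in 1:60) {
    tab <- uniform_table(0)
    tab[] <- round(runif(400, -1, 1), 3)
    tab[] <- (tab + t(tab)) / 2
    Li <- sample(2:8, 1); Lj <- sample(2:8, 1)
    ri <- sample(aa, Li, replace = TRUE)
    rj <- sample(aa, Lj, replace = TRUE)
    p <- toy_protein(c(paste(ri, collapse = ""), paste(rj, collapse = ""),
                       "VVV"))
    for (o in c("A", "P")) {
      al <- align_pair(p$strands[1, ], p$strands[2, ], o, tab, cfg)
      orc <- oracle_best_alignment(ri, rj, o, tab)
      expect_equal(al$raw_score, orc$score, tolerance = 1e-10)
      # monotone register: antiparallel decreasing, parallel increasing
      if (nrow(al$pairs) > 1) {
        d <- diff(al$pairs[, 2])
        if (o == "A") expect_true(all(d == -1)) else expect_true(all(d == 1))
      }
    }
  }
})

test_that("locality correction applies the per-separation weights", {
  cfg <- default_config()   # weight 0.9 at separation 1, 1.0 beyond
  expect_equal(locality_correct(10, 1, 6, cfg), 10)
  expect_equal(locality_correct(10, 1, 2, cfg), 9)
  expect_equal(locality_correct(10, 3, 4, default_config(
    locality_weights = c(0.5, 0.8, 1))), 5)
  # monotone for positive raw under the default ordering
  expect_lte(locality_correct(10, 1, 2, cfg), locality_correct(10, 1, 4, cfg))
  expect_error(locality_correct(10, 3, 2, cfg))
})

test_that("score_all_pairs is complete, symmetric and scale-equivariant", {
  cfg <- default_config()
  p <- toy_protein(c("VIVI", "IVIV", "VIVI"))
  sp <- score_all_pairs(p, uniform_table(1), cfg)
  expect_lte(length(sp$alignments), 6L)    # 3 pairs x 2 orientations
  expect_identical(sp_get(sp, 2, 1, "A"), sp_get(sp, 1, 2, "A"))

  # renaming the protein does not change scores (purity)
  p2 <- p; p2$id <- "other"
  sp2 <- score_all_pairs(p2, uniform_table(1), cfg)
  expect_equal(sp2$alignments, sp$alignments)

  # multiplying the table by c > 0 multiplies every raw score by c
  tab <- uniform_table(0); set.seed(7)
  tab[] <- round(runif(400, -1, 1), 3); tab[] <- (tab + t(tab)) / 2
  spa <- score_all_pairs(p, tab, cfg)
  spb <- score_all_pairs(p, tab * 3, cfg)
  for (k in names(spa$alignments)) {
    expect_equal(spb$alignments[[k]]$raw_score,
                 3 * spa$alignments[[k]]$raw_score, tolerance = 1e-9)
  }

  two <- protein_record("p", "VIVIVIVIV",
                        strands = data.frame(start = c(1, 5), end = c(3, 7)))
  expect_error(score_all_pairs(two, uniform_table(1), cfg),
               "at least 3 strands")
})

test_that("potential tables round-trip through TSV and validate", {
  tab <- default_potential()
  expect_equal(tab, t(tab), ignore_attr = TRUE)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_potential_table(tab, tf)
  back <- read_potential_table(tf)
  expect_equal(unclass(back)[, ], unclass(tab)[, ], tolerance = 1e-9)

  bad <- tab; bad["A", "V"] <- bad["A", "V"] + 1   # break symmetry
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(cbind(data.frame(aa = rownames(bad)), as.data.frame(bad)),
              tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_potential_table(tf2), "symmetric")
})
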