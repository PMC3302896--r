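test_that("the binary-program solver matches brute force on random programs", {
  set.seed(11)
  for (trial in 1:40) {
    nv <- sample(3:10, 1)
    obj <- round(runif(nv, -2, 3), 3)
    m <- sample(1:6, 1)
    rows <- lapply(seq_len(m), function(r) {
      k <- sample(seq_len(nv), sample(2:nv, 1))
      coef <- round(runif(length(k), -2, 2), 2)
      bnd <- sort(round(runif(2, -2, 3), 2))
      if (runif(1) < 0.3) bnd[1] <- -Inf
      if (runif(1) < 0.3) bnd[2] <- Inf
      list(idx = k, coef = coef, lo = bnd[1], hi = bnd[2])
    })
    sol <- solve_binary_program(obj, rows)
    # exhaustive reference
    grid <- as.matrix(expand.grid(rep(list(0:1), nv)))
    feas <- rep(TRUE, nrow(grid))
    for (rw in rows) {
      act <- grid[, rw$idx, drop = FALSE] %*% rw$coef
      feas <- feas & act >= rw$lo - 1e-9 & act <= rw$hi + 1e-9
    }
    if (!any(feas)) {
      expect_equal(sol$status, "infeasible")
    } else {
      expect_equal(sol$status, "optimal")
      expect_equal(sol$objective, max(grid[feas, ] %*% obj), tolerance = 1e-9)
      act_ok <- all(vapply(rows, function(rw) {
        a <- sum(rw$coef * sol$x[rw$idx])
        a >= rw$lo - 1e-9 && a <= rw$hi + 1e-9
      }, logical(1)))
      expect_true(act_ok)
    }
  }
})

test_that("model construction counts variables and installs the contact cap", {
  cfg <- default_config()
  p <- toy_protein(c("VIVIV", "IVIVI", "VIVIV"))
  sp <- score_all_pairs(p, uniform_table(1), cfg)
  m <- build_model(p, sp, cfg)
  expect_equal(sum(m$vars$kind == "y"), 6L)   # 3 pairs x 2 orientations
  labs <- vapply(m$rows, `[[`, character(1), "label")
  tot <- m$rows[[which(labs == "total_contacts")]]
  expect_equal(tot$hi, 2)                     # N - 1 with N = 3
  p4 <- toy_protein(c("VIVIV", "IVIVI", "VIVIV", "IVIVI"))
  sp4 <- score_all_pairs(p4, uniform_table(1), cfg)
  m4 <- build_model(p4, sp4, cfg)
  labs4 <- vapply(m4$rows, `[[`, character(1), "label")
  expect_equal(m4$rows[[which(labs4 == "total_contacts")]]$hi, 3)
  # all-zero assignment has objective 0 (empty sum)
  expect_equal(sum(m$obj * 0), 0)
})

test_that("hydrogen-bond bounds follow the 0.638 coefficient and 15% band", {
  # 40 strand residues: target 25.52, window [22, 29]
  p <- toy_protein(c(strrep("V", 10), strrep("I", 10),
                     strrep("V", 10), strrep("I", 10)))
  expect_equal(sum(p$strands$length), 40L)
  b <- hbond_bounds(p, default_config())
  expect_equal(unname(b), c(22, 29))
  # zero tolerance forces the rounded target and warns when empty
  expect_warning(b0 <- hbond_bounds(p, default_config(hbond_tolerance = 1e-9)),
                 "window empty")
  expect_equal(unname(b0), c(26, 26))
})

test_that("integer cuts exclude the incumbent and yield distinct solutions", {
  cfg <- default_config(K = 4)
  fx <- suppressWarnings(make_fixture(4, seed = 5, config = cfg))
  sols <- solve_ranked(fx$protein, fx$scored_pairs, cfg)
  expect_gte(length(sols), 2L)
  keys <- vapply(sols, function(tp)
    paste(vapply(tp$contacts, function(ct)
      paste(ct$i, ct$j, ct$orientation), character(1)), collapse = "|"),
    character(1))
  expect_equal(anyDuplicated(keys), 0L)
  objs <- vapply(sols, `[[`, numeric(1), "objective")
  expect_true(all(diff(objs) <= 1e-9))     # non-increasing with rank
  expect_equal(vapply(sols, `[[`, integer(1), "rank"), seq_along(sols))
})

test_that("a 3-strand toy with uniform scores yields a 2-contact path", {
  cfg <- relaxed_config(K = 3)
  p <- toy_protein(c("VIVIV", "IVIVI", "VIVIV"))
  sp <- score_all_pairs(p, uniform_table(1), cfg)
  sols <- solve_ranked(p, sp, cfg)
  expect_gte(length(sols), 1L)
  for (s in sols) expect_lte(length(s$contacts), 2L)
  expect_equal(length(sols[[1]]$contacts), 2L)
  # K = 1 returns exactly the optimum
  one <- solve_ranked(p, sp, relaxed_config(K = 1))
  expect_equal(length(one), 1L)
  expect_equal(one[[1]]$objective, sols[[1]]$objective)
})

test_that("a strand without alignable partners is diagnosed at build time", {
  cfg <- default_config()
  p <- protein_record("p", "GGVIVGGGIVIGGGVGG",
                      strands = data.frame(start = c(3, 9, 15),
                                           end = c(5, 11, 15)))
  sp <- score_all_pairs(p, uniform_table(1), cfg)
  expect_error(build_model(p, sp, cfg), "strand 3")
})
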