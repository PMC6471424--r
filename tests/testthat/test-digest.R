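test_that("site finding is circular, strand-aware and IUPAC-aware", {
  ecoRI <- enzyme_def("EcoRI", "GAATTC", 1, 5)
  g <- genome("toy", "GAATTCAAGAATTCAA")
  expect_equal(find_sites(g, ecoRI), c(1L, 9L))

  # site spanning the origin: ...GAA | TTC...
  g2 <- genome("wrap", paste0("TTCAAACCCGGGAAAG", "AA"))
  expect_equal(find_sites(g2, ecoRI), 16L)
  # same sequence linear: no site
  g2l <- genome("wrapl", g2$seq, topology = "linear")
  expect_length(find_sites(g2l, ecoRI), 0L)

  # degenerate site GGWCC matches both GGACC and GGTCC
  set.seed(5)
  s <- random_dna(2000)
  avaII <- enzyme_def("AvaII", "GGWCC", 1, 4)
  lens <- sort(digest_circular(genome("d", s), avaII)$length)
  expect_equal(lens, sort(oracle_circular_digest(s, "GGWCC", 1L)))

  # non-palindromic enzyme: both strands are searched
  g3 <- genome("np", paste0("AAAACCTGCAAAA", "AAGCAGGTAAAA"))
  hits <- find_sites(g3, enzyme_def("Tst", "ACCTGC", 2, 4))
  expect_length(hits, 2L)
})

test_that("circular digestion conserves length", {
  ecoRI <- enzyme_def("EcoRI", "GAATTC", 1, 5)
  g0 <- genome("none", strrep("ACGG", 25))
  dg0 <- digest_circular(g0, ecoRI)
  expect_equal(nrow(dg0), 1L)
  expect_equal(dg0$length, 100L)

  # two cut points at 10 and 30 on a 100-nt circle -> lengths 20 and 80
  s <- strrep("C", 100)
  substr(s, 10, 15) <- "GAATTC"; substr(s, 30, 35) <- "GAATTC"
  g <- genome("two", s)
  dg <- digest_circular(g, ecoRI)
  expect_equal(sort(dg$length), c(20L, 80L))
  expect_equal(sum(dg$length), 100L)

  # random toys: n sites -> n fragments summing to L, equal to the
  # doubled-sequence oracle
  set.seed(20)
  for (i in 1:5) {
    s <- random_dna(1500, gc = 0.4)
    g <- genome("r", s)
    dg <- digest_circular(g, ecoRI)
    expect_equal(sum(dg$length), 1500L)
    expect_equal(sort(dg$length),
                 sort(oracle_circular_digest(s, "GAATTC", 1L)))
  }
})

test_that("fixed-start prediction at r = 0 reduces to a linear digest", {
  set.seed(21)
  s <- random_dna(3000, gc = 0.45)
  g <- genome("g", s)
  ecoRI <- enzyme_def("EcoRI", "GAATTC", 1, 5)
  pm <- packaging_model(3000, 0, pac_position = 1234)
  bt <- predict_band_table(g, ecoRI, pm, start_model = "fixed")
  expect_equal(sum(bt$length), 3000L)
  # exactly the two pac-flanking end pieces are submolar, no junction
  expect_equal(sum(bt$cls == "terminal_submolar"), 2L)
  expect_equal(sum(bt$cls == "junction_only"), 0L)
  expect_true(all(bt$cls[bt$cls != "terminal_submolar"] == "core"))
  # the two terminal pieces together make up the pac-spanning fragment
  dg <- digest_circular(g, ecoRI)
  cuts <- attr(dg, "cuts")
  spans <- dg[dg$start <= 1234 & dg$start + dg$length > 1234, ]
  term <- bt$length[bt$cls == "terminal_submolar"]
  expect_equal(sum(term), spans$length)
})

test_that("uniform-permutation molarity matches exhaustive enumeration", {
  set.seed(22)
  s <- random_dna(800, gc = 0.4)
  g <- genome("g", s)
  ecoRI <- enzyme_def("EcoRI", "GAATTC", 1, 5)
  for (r in c(0, 0.08)) {
    pm <- packaging_model(800, r, pac_position = 101)
    bt <- predict_band_table(g, ecoRI, pm, start_model = "uniform")
    L <- 800L; w <- as.integer(round(L * (1 + r)))
    # enumeration over all L virion starts
    big <- paste0(s, s, s)
    for (k in seq_len(nrow(bt))) {
      if (bt$cls[k] == "junction_only" && bt$length[k] == w) next
      frag <- substr(paste0(s, s), bt$start[k],
                     bt$start[k] + bt$length[k] - 1L)
      hits <- 0L
      for (st in seq_len(L)) {
        vir <- substr(big, st, st + w - 1L)
        if (grepl(frag, vir, fixed = TRUE)) hits <- hits + 1L
      }
      expect_equal(bt$molarity[k], hits / L, tolerance = 1e-12)
    }
    # and at r = 0 the closed form (L - len + 1)/L holds for all bands
    if (r == 0) {
      expect_equal(bt$molarity, (L - bt$length + 1) / L)
      expect_true(all(bt$cls == "terminal_submolar"))
    }
  }
})

test_that("series-model molarity matches Monte-Carlo virion sampling", {
  set.seed(23)
  s <- random_dna(2000, gc = 0.42)
  g <- genome("g", s)
  mboI <- enzyme_def("MboI", "GATC", 0, 4)
  pm <- packaging_model(2000, 0.13, pac_position = 46)
  bt <- predict_band_table(g, mboI, pm, start_model = "series")
  expect_gt(nrow(bt), 2L)
  n <- 1e5
  starts <- simulate_virion_population(g, pm, n, seed = 99,
                                       return = "starts")
  w <- as.integer(round(2000 * 1.13))
  for (k in seq_len(nrow(bt))) {
    a <- bt$start[k]; len <- bt$length[k]
    t <- (a - starts) %% 2000L
    p_mc <- mean(t <= w - len)
    sigma <- sqrt(max(bt$molarity[k] * (1 - bt$molarity[k]), 1e-9) / n)
    expect_lte(abs(p_mc - bt$molarity[k]), 3 * sigma + 1e-9)
  }
})

test_that("virion digests conserve the packaged length", {
  set.seed(24)
  s <- random_dna(1200, gc = 0.35)
  g <- genome("g", s)
  pm <- packaging_model(1200, 0.15, pac_position = 500)
  virions <- simulate_virion_population(g, pm, 8, seed = 3)
  w <- as.integer(round(1200 * 1.15))
  for (v in virions) {
    # linear digest of the virion molecule itself
    cutpos <- integer(0)
    for (p in seq_len(nchar(v) - 5L)) {
      if (substr(v, p, p + 5L) == "GAATTC") cutpos <- c(cutpos, p)  # cut after p
    }
    pieces <- diff(c(0L, cutpos, nchar(v)))
    expect_equal(sum(pieces), w)
  }
})

test_that("junction bands appear only in longer-than-unit genomes", {
  # toy: 200-nt circle, cuts flanking pac such that the pac-spanning
  # fragment needs terminal redundancy to be packaged intact
  s <- strrep("C", 200)
  substr(s, 50, 55) <- "GAATTC"
  substr(s, 150, 155) <- "GAATTC"
  g <- genome("toy", s)
  ecoRI <- enzyme_def("EcoRI", "GAATTC", 1, 5)
  # pac inside the fragment that spans position 1
  pm0 <- packaging_model(200, 0, pac_position = 180)
  bt0 <- predict_band_table(g, ecoRI, pm0, start_model = "fixed")
  expect_equal(sum(bt0$cls == "junction_only"), 0L)
  # with r = 0.5 the redundancy reaches past the junction fragment end
  pm1 <- packaging_model(200, 0.5, pac_position = 180)
  bt1 <- predict_band_table(g, ecoRI, pm1, start_model = "fixed")
  jx <- bt1[bt1$cls == "junction_only", ]
  expect_equal(nrow(jx), 1L)
  # it is exactly the circular fragment spanning the linearisation
  # point, absent from the unit-length linear digest
  dg <- digest_circular(g, ecoRI)
  span_len <- dg$length[dg$start == 151]
  expect_equal(jx$length, span_len)
  # enumeration: the virion sequence contains the intact fragment
  vir <- substr(paste0(s, s), 180, 180 + 300 - 1)
  frag <- substr(paste0(s, s), 151, 151 + span_len - 1)
  expect_true(grepl(frag, vir, fixed = TRUE))
})

test_that("gel matching pairs bands within tolerance", {
  m <- match_gel(c(10000, 5000, 2000), c(10100, 4900, 2000),
                 rel_tol = 0.05)
  expect_equal(nrow(m$matches), 3L)
  expect_equal(nrow(m$unmatched_predicted), 0L)
  expect_length(m$unmatched_observed, 0L)

  # a submolar terminal fragment missing from the gel is reported with
  # its class (the "white triangle" case)
  pred <- data.frame(length = c(8000, 3000, 1200),
                     cls = c("core", "core", "terminal_submolar"))
  m2 <- match_gel(pred, c(8050, 2980), rel_tol = 0.05)
  expect_equal(m2$unmatched_predicted$length, 1200)
  expect_equal(m2$unmatched_predicted$cls, "terminal_submolar")

  # co-migrating predictions share one observed band
  m3 <- match_gel(c(4000, 4050), c(4020), rel_tol = 0.05)
  expect_equal(nrow(m3$matches), 2L)
  expect_equal(unique(m3$matches$observed), 4020)
  expect_equal(sum(m3$matches$shared), 1L)
  expect_length(m3$unmatched_observed, 0L)
  # exact self-match never leaves residuals despite co-migration
  set.seed(99)
  lens <- sample(200:5000, 25)
  m5 <- match_gel(lens, lens, rel_tol = 0.05)
  expect_equal(nrow(m5$unmatched_predicted), 0L)
  expect_length(m5$unmatched_observed, 0L)

  # each observed band is used at most once
  m4 <- match_gel(c(1000), c(1010, 990), rel_tol = 0.05)
  expect_equal(nrow(m4$matches), 1L)
  expect_length(m4$unmatched_observed, 1L)
  expect_error(match_gel(numeric(0), c(1)), "empty")
  expect_error(match_gel(c(1), c(1), rel_tol = 0.3), "rel_tol")
})

test_that("grid search recovers packaging parameters from band tables", {
  sim <- simulate_genome(genome_spec(5000, gc_target = 0.45, seed = 31,
                                     module_layout = data.frame(
                                       module = "m", strand = "+",
                                       n_genes = 3L, mean_len = 600)))
  g <- sim$genome
  enz <- list(enzyme_def("MboI", "GATC", 0, 4),
              enzyme_def("HaeIII", "GGCC", 2, 2))
  # require a usable number of sites for both enzymes
  expect_gte(length(find_sites(g, enz[[1]])), 3L)
  expect_gte(length(find_sites(g, enz[[2]])), 3L)
  true_pac <- 1500L; true_r <- 0.1
  pm_true <- packaging_model(5000, true_r, true_pac)
  observed <- lapply(enz, function(e) {
    bt <- predict_band_table(g, e, pm_true, start_model = "series")
    vis <- bt$length[bt$molarity >= 0.15 & bt$resolvable]
    band_list(vis, unit = "nt", source = "observed")
  })
  fit <- fit_packaging(g, enz, observed,
                       pac_grid = seq(100L, 4900L, by = 200L),
                       r_grid = c(0, 0.05, 0.1, 0.2))
  best <- fit$grid[fit$grid$score == fit$score, , drop = FALSE]
  # the true parameters are among the minimisers, close to the truth
  expect_true(any(best$r == true_r & abs(best$pac - true_pac) <= 200L))
  expect_equal(coef(fit), fit$par)
})
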