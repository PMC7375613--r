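test_that("rsdr: ratio, demand floor, zero supply", {
  st <- resource_state(70000, c(t1 = 10))
  st$init_demand <- 7000
  expect_equal(rsdr(st), 10)
  st$init_demand <- 0
  expect_equal(rsdr(st), 70000)   # demand floored at 1
  st$G_free <- 0
  expect_equal(rsdr(st), 0)
})

test_that("effective_demand is the alpha-weighted awaiting-codon count", {
  tb <- build_recognition_table(
    data.frame(codon = c("GGG", "GGA"), trna_id = c("tA", "tA"),
               alpha = c(1, 0.5)), partial = TRUE)
  st <- resource_state(10, c(tA = 100))
  expect_equal(effective_demand("tA", st, tb), 0)
  st$codon_demand[["GGG"]] <- 4
  expect_equal(effective_demand("tA", st, tb), 4)
  st$codon_demand[["GGA"]] <- 2
  expect_equal(effective_demand("tA", st, tb), 5)  # 1*4 + 0.5*2
  expect_error(effective_demand("nope", st, tb), "unknown")
})

test_that("esdr limit cases match the closed forms to machine precision", {
  tb <- build_recognition_table(
    data.frame(codon = "GGG", trna_id = "tA", alpha = 0.5), partial = TRUE)
  st <- resource_state(10, c(tA = 100))
  st$codon_demand[["GGG"]] <- 16   # D_tA = 0.5 * 16 = 8

  # d_c = 0: exponent 0, demand ignored entirely
  expect_identical(esdr("GGG", st, tb, rec_zero()), 0.5 * 100)

  # w*d -> infinity: exponent 1 exactly (in floating point), full division
  rec1 <- recycling_params(stats::setNames(rep(1, 61), sense_codons()),
                           w = 800)
  expect_identical(esdr("GGG", st, tb, rec1), 0.5 * 100 / 8)

  # exponent 1/2: alpha*H / sqrt(D)
  rec_half <- recycling_params(
    stats::setNames(rep(log(2), 61), sense_codons()), w = 1)
  st$codon_demand[["GGG"]] <- 32   # D = 16, sqrt = 4
  expect_equal(esdr("GGG", st, tb, rec_half), 0.5 * 100 / 4)

  expect_error(esdr("UAA", st, tb, rec_zero()), "stop")
})

test_that("esdr monotonicity in supply and demand", {
  tb <- ggg_table()
  rec_half <- recycling_params(
    stats::setNames(rep(log(2), 61), sense_codons()), w = 1)
  st <- resource_state(10, c(`tRNA-Gly-CCC` = 50, `tRNA-Gly-UCC` = 50))
  st$codon_demand[["GGG"]] <- 10
  base <- esdr("GGG", st, tb, rec_half)
  st$H_free[["tRNA-Gly-CCC"]] <- 80
  expect_gt(esdr("GGG", st, tb, rec_half), base)
  st$codon_demand[["GGG"]] <- 40
  expect_lt(esdr("GGG", st, tb, rec_half), base)
  expect_true(all(rec_half$exponent >= 0 & rec_half$exponent < 1))
})

test_that("allocate_trna: proportional choice, exhaustion, conservation", {
  tb <- ggg_table()
  st <- resource_state(10, c(`tRNA-Gly-CCC` = 90, `tRNA-Gly-UCC` = 20))

  # single decoder: deterministic pick and decrement
  tb1 <- build_recognition_table(
    data.frame(codon = "GGG", trna_id = "tA", alpha = 1), partial = TRUE)
  st1 <- resource_state(10, c(tA = 5))
  expect_equal(allocate_trna("GGG", st1, tb1), "tA")
  expect_equal(unname(st1$H_free[["tA"]]), 4)

  # weighted frequency: alpha*H = {90, 10} -> P(CCC) = 0.9
  set.seed(99)
  hits <- 0L
  for (i in 1:10000) {
    j <- allocate_trna("GGG", st, tb)
    hits <- hits + (j == "tRNA-Gly-CCC")
    release_trna(j, st)  # restore for the next draw
  }
  expect_equal(hits / 10000, 0.9, tolerance = 0.012)

  # exhausted decoders: NULL, no mutation
  st0 <- resource_state(10, c(`tRNA-Gly-CCC` = 0, `tRNA-Gly-UCC` = 0))
  before <- as.list(st0$H_free)
  expect_null(allocate_trna("GGG", st0, tb))
  expect_identical(as.list(st0$H_free), before)
})

test_that("release_trna: round-trip identity and accounting errors", {
  tb <- ggg_table()
  st <- resource_state(10, c(`tRNA-Gly-CCC` = 3, `tRNA-Gly-UCC` = 3))
  h0 <- st$H_free
  j <- allocate_trna("GGG", st, tb)
  release_trna(j, st)
  expect_identical(st$H_free, h0)
  expect_error(release_trna("tRNA-Gly-CCC", st), "accounting")

  # randomized invariant sweep: H_free + bound constant throughout
  set.seed(5)
  for (i in 1:1000) {
    j <- allocate_trna("GGG", st, tb)
    if (runif(1) < 0.6 && !is.null(j)) release_trna(j, st)
    expect_true(all(st$H_free + st$bound_trna == st$H_tot_per))
  }
})

test_that("distance_scores: cap rule, homopolymer, brute-force oracle", {
  tb <- wc_table()

  # homopolymeric ORF: nearest co-decoded neighbor is adjacent -> d = 1
  rp <- distance_scores(list(list(codons = rep("GCU", 12), copies = 1)), tb)
  expect_equal(unname(rp$d[["GCU"]]), 1)

  # singleton occurrence: distance to ORF end (inclusive cap)
  orf <- c("AUG", rep("GCU", 5), "UGG", rep("GCU", 3))
  rp2 <- distance_scores(list(list(codons = orf, copies = 1)), tb)
  expect_equal(unname(rp2$d[["UGG"]]), length(orf) - 7 + 1)
  expect_equal(unname(rp2$d[["AUG"]]), length(orf))

  # toy 2-gene transcriptome vs an independent per-occurrence scan
  tb2 <- default_recognition_table()
  set.seed(3)
  tx <- list(list(codons = random_orf(25), copies = 2),
             list(codons = random_orf(30), copies = 5))
  rp3 <- distance_scores(tx, tb2)

  co <- (tb2$alpha > 0) %*% t(tb2$alpha > 0) > 0
  num <- den <- stats::setNames(numeric(61), sense_codons())
  for (g in tx) {
    ids <- match(g$codons, sense_codons())
    L <- length(ids)
    for (p in seq_len(L)) {
      d <- L - p + 1
      q <- p + 1
      while (q <= L) {
        if (co[ids[p], ids[q]]) { d <- q - p; break }
        q <- q + 1
      }
      num[ids[p]] <- num[ids[p]] + g$copies * d
      den[ids[p]] <- den[ids[p]] + g$copies
    }
  }
  seen <- den > 0
  expect_equal(rp3$d[seen], (num / den)[seen])
  # normalization: the median distance score maps to exponent one half
  expect_equal(1 - exp(-rp3$w * stats::median(rp3$d)), 0.5,
               tolerance = 1e-9)
})
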