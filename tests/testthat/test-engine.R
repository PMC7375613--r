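test_that("set_timer: arithmetic, monotonicity, degenerate supply", {
  expect_equal(set_timer(10, scale = 1, dt = 0.05), 2L)  # 0.1 s
  expect_equal(set_timer(20, scale = 1, dt = 0.05), 1L)  # halved, floored
  t1 <- set_timer(4, scale = 2, dt = 0.05)
  t2 <- set_timer(8, scale = 2, dt = 0.05)
  expect_lte(t2, t1)
  expect_true(is.finite(set_timer(0, scale = 1, dt = 0.05)))
  # monotone nonincreasing over a sweep
  ticks <- set_timer(seq(0.1, 50, length.out = 200), scale = 5, dt = 0.05)
  expect_true(all(diff(ticks) <= 0))
})

test_that("initiation fires after round(local_init/dt) ticks at neutral RSDR", {
  # one empty lattice, plentiful ribosomes; rsdr_ref = G_tot makes the
  # waiting ribosome see exactly its local initiation time
  w <- engine_world(list(rep("GCU", 30)), init_time = 0.95, G_tot = 50,
                    cfg = engine_config(rsdr_ref = 50))
  out <- run_world(w, ticks = 40)
  first_init <- which(out$traj$n_init > 0)[1L]
  expect_equal(first_init, 1L + round(0.95 / 0.05))
})

test_that("single-particle closed form: per-protein time = init + codon waits", {
  # G_tot = 1 admits exactly one ribosome; per-species pools chosen away
  # from tick rounding boundaries so +/- 2 bound molecules cannot shift
  # the quantized wait (H in {50, 100, 250, 500} -> 10, 5, 2, 1 ticks at
  # scale 25, dt 0.05)
  tb <- wc_table()
  cfg <- engine_config(rsdr_ref = 1, scale_elong = 25)
  set.seed(1234)
  H <- stats::setNames(sample(c(50, 100, 250, 500), length(tb$trna_ids),
                              replace = TRUE), tb$trna_ids)
  for (i in 1:20) {
    orf <- random_orf(sample(10:30, 1))
    init_time <- round(runif(1, 0.2, 2) / 0.05) * 0.05
    lat <- mrna_lattice(orf, "g", init_time)
    waits <- set_timer(H[paste0("t_", orf)], cfg$scale_elong, cfg$dt)
    expected <- 1L + round(init_time / cfg$dt) +
      sum(waits + cfg$transloc_ticks)
    out <- run_engine(list(lat), tb, rec_zero(), cfg, G_tot = 1,
                      H_tot_per = H, ticks = expected + 10L)
    measured <- out$term_ticks[["g"]][1L]
    expect_lte(abs(measured - expected), 1L)
  }
})

test_that("blocked ribosomes respect the footprint boundary exactly", {
  # downstream ribosome stalls forever on a codon whose only decoder has
  # zero molecules; the trailing ribosome must stop at gap exactly s
  tb <- wc_table()
  s <- 5L
  orf <- c(rep("GCU", 30), "CCG", rep("GCU", 10))  # stall at position 31
  H <- full_pool(tb, 1000)
  H[["t_CCG"]] <- 0
  cfg <- engine_config(s = s, rsdr_ref = 10)
  lat <- mrna_lattice(orf, "g", 0.2)
  set.seed(2)
  out <- run_engine(list(lat), tb, rec_zero(), cfg, G_tot = 10,
                    H_tot_per = H, ticks = 600, record_positions = TRUE)
  v <- count_violations(out$positions, s)
  expect_equal(unname(v["gap"]), 0L)
  expect_equal(unname(v["order"]), 0L)
  final <- out$final$ribosomes[[1L]]
  pos <- sort(final[, "pos"], decreasing = TRUE)
  expect_equal(pos[1L], 31L)                  # stalled at the bare codon
  expect_equal(diff(sort(final[, "pos"])), rep(s, nrow(final) - 1L))
})

test_that("termination conserves ribosomes within the tick", {
  w <- engine_world(list(rep("GCU", 12)), init_time = 0.3, G_tot = 7)
  out <- run_world(w, 400)
  tr <- out$traj
  expect_true(all(tr$G_free + tr$bound_ribo == 7))
  expect_gt(sum(tr$n_term), 0)
})

test_that("identical config + seed give bit-identical event streams", {
  cell <- toy_cell(seed = 3, run_ticks = 300)
  set.seed(42)
  a <- run_simulation(cell$cfg, cell$lattices, cell$table, cell$rec,
                      ticks = 300)
  set.seed(42)
  b <- run_simulation(cell$cfg, cell$lattices, cell$table, cell$rec,
                      ticks = 300)
  expect_identical(a$traj, b$traj)
  expect_identical(a$term_ticks, b$term_ticks)
  expect_identical(a$occupancy, b$occupancy)
  expect_identical(a$esdr_mean, b$esdr_mean)
})

test_that("uniform random visiting order: two mRNAs share one ribosome", {
  # one free ribosome, two identical mRNAs: over many independent seeded
  # runs, each mRNA wins the first placement about half the time
  tb <- wc_table()
  cfg <- engine_config(rsdr_ref = 1)
  H <- full_pool(tb, 500)
  lats <- list(mrna_lattice(rep("GCU", 40), "a", 0.2),
               mrna_lattice(rep("GCU", 40), "b", 0.2))
  wins_a <- 0L
  n <- 400L
  for (i in seq_len(n)) {
    set.seed(i)
    out <- run_engine(lats, tb, rec_zero(), cfg, G_tot = 1,
                      H_tot_per = H, ticks = 8)
    stopifnot(sum(out$traj$n_init) == 1)
    got_a <- nrow(out$final$ribosomes[[1L]]) == 1L
    wins_a <- wins_a + got_a
  }
  expect_equal(wins_a / n, 0.5, tolerance = 0.07)
})

test_that("starvation monotonicity: fewer decoding tRNAs, no more protein", {
  tb <- wc_table()
  cfg <- engine_config(rsdr_ref = 20)
  lats <- lapply(1:5, function(i) mrna_lattice(rep("GCU", 30), "g", 0.3))
  terms <- vapply(c(200, 50, 10), function(h) {
    H <- full_pool(tb, 1000)
    H[["t_GCU"]] <- h
    set.seed(9)
    out <- run_engine(lats, tb, rec_zero(), cfg, G_tot = 20,
                      H_tot_per = H, ticks = 1500)
    length(out$term_ticks[["g"]])
  }, 0L)
  expect_true(all(diff(terms) <= 0))
  expect_gt(terms[1L], 0L)
})

test_that("zero-demand warning counter flags pathological waits", {
  tb <- wc_table()
  H <- full_pool(tb, 1000)
  H[["t_CCG"]] <- 0   # unservable codon -> ESDR 0 -> wait above the bound
  lat <- mrna_lattice(c(rep("GCU", 5), "CCG"), "g", 0.2)
  set.seed(1)
  out <- run_engine(list(lat), tb, rec_zero(),
                    engine_config(rsdr_ref = 5, warn_wait = 10),
                    G_tot = 5, H_tot_per = H, ticks = 200)
  expect_gt(out$warn_count, 0)
})
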