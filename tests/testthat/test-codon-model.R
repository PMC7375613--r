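test_that("recognition table construction: coefficients, rt, coverage", {
  # single Watson-Crick decoder
  tb <- build_recognition_table(
    data.frame(codon = "UGG", trna_id = "tRNA-Trp-CCA",
               class = "watson_crick"), partial = TRUE)
  expect_equal(tb$alpha["UGG", "tRNA-Trp-CCA"], 1.0)
  expect_equal(tb$rt[["UGG"]], "tRNA-Trp-CCA")

  # two decoders with distinct classes
  tb2 <- ggg_table()
  expect_length(tb2$rt[["GGG"]], 2L)
  expect_equal(sort(unname(tb2$alpha["GGG", tb2$rt[["GGG"]]])), c(0.5, 1.0))

  # dropping all decoders of AUA must name the codon
  rules <- default_wobble_rules()
  expect_error(
    build_recognition_table(rules[rules$codon != "AUA", ]),
    "AUA")

  # coefficient range enforced
  expect_error(build_recognition_table(
    data.frame(codon = "UGG", trna_id = "x", alpha = 1.5), partial = TRUE),
    "\\(0, 1\\]")
  expect_error(build_recognition_table(
    data.frame(codon = "UGG", trna_id = "x", alpha = 0), partial = TRUE),
    "\\(0, 1\\]")

  # stop codons rejected
  expect_error(build_recognition_table(
    data.frame(codon = "UAA", trna_id = "x", alpha = 1), partial = TRUE),
    "UAA")
})

test_that("default table covers all codons and shares species as expected", {
  tb <- default_recognition_table()
  expect_true(all(lengths(tb$rt) >= 1L))
  # canonical split-box sharing: UCC reads GGA and GGG, GCC reads GGU and GGC
  expect_setequal(names(which(tb$alpha[, "tRNA-Gly-UCC"] > 0)),
                  c("GGA", "GGG"))
  expect_setequal(names(which(tb$alpha[, "tRNA-Gly-GCC"] > 0)),
                  c("GGU", "GGC"))
})

test_that("tai_weights: normalization, hand-computed case, zero handling", {
  # one codon, one decoder: self-normalizes to 1
  tb <- build_recognition_table(
    data.frame(codon = "UGG", trna_id = "t1", alpha = 1), partial = TRUE)
  w <- tai_weights(tb, c(t1 = 10))
  expect_equal(unname(unclass(w)["UGG"]), 1.0)

  # W = {20, 5} -> weights {1, 0.25}
  tb2 <- build_recognition_table(
    data.frame(codon = c("GGG", "GGG", "GGA"),
               trna_id = c("tA", "tB", "tC"),
               alpha = c(1, 0.5, 0.5)), partial = TRUE)
  w2 <- tai_weights(tb2, c(tA = 15, tB = 10, tC = 10))  # W: GGG=20, GGA=5
  expect_equal(unname(unclass(w2)[c("GGG", "GGA")]), c(1.0, 0.25))

  # codon whose decoders all have level 0 gets the geometric mean of the
  # nonzero normalized weights
  w3 <- tai_weights(tb2, c(tA = 15, tB = 10, tC = 0))
  expect_equal(unname(unclass(w3)["GGA"]),
               exp(mean(log(1.0))))  # only GGG is nonzero
  expect_error(tai_weights(tb2, c(tA = 0, tB = 0, tC = 0)), "zero")
})

test_that("tai_of_sequence: geometric mean, errors", {
  tb <- build_recognition_table(
    data.frame(codon = c("GGG", "GGA"), trna_id = c("tA", "tC"),
               alpha = c(1, 1)), partial = TRUE)
  w <- tai_weights(tb, c(tA = 20, tC = 5))
  expect_equal(tai_of_sequence(c("GGG", "GGG"), w), 1.0)
  expect_equal(tai_of_sequence(c("GGG", "GGA"), w), 0.5)  # sqrt(1 * 0.25)
  expect_error(tai_of_sequence(character(0), w), "empty")
  expect_error(tai_of_sequence(c("GGG", "UAA"), w), "stop")
})

test_that("tAI invariances: codon permutation and pool scaling", {
  tb <- default_recognition_table()
  set.seed(42)
  lv <- stats::setNames(runif(length(tb$trna_ids), 10, 100), tb$trna_ids)
  w <- tai_weights(tb, lv)
  orf <- random_orf(40)
  expect_equal(tai_of_sequence(orf, w), tai_of_sequence(sample(orf), w))
  expect_equal(unclass(tai_weights(tb, lv * 7.3)), unclass(w))
})

test_that("CAI weights and scores", {
  # reference: GGG x30, GGA x10 -> w(GGA) = 1/3
  ref <- list(c(rep("GGG", 30), rep("GGA", 10)))
  w <- cai_weights(ref)
  expect_equal(unname(unclass(w)["GGA"]), 1 / 3)
  expect_equal(unname(unclass(w)["GGG"]), 1.0)
  expect_equal(cai_of_sequence(c("GGA"), w), 1 / 3)
  # ORF of only family-maximal codons scores 1
  expect_equal(cai_of_sequence(c("GGG", "GGG"), w), 1.0)
  # one-codon family is degenerate: always 1
  expect_equal(cai_of_sequence("AUG", cai_weights(list(c("AUG", "GGG")))),
               1.0)
})

test_that("coefficient optimization recovers a planted wobble coefficient", {
  tb <- default_recognition_table()
  set.seed(7)
  lv <- stats::setNames(runif(length(tb$trna_ids), 5, 80), tb$trna_ids)
  orfs <- lapply(1:25, function(i) random_orf(50))

  # plant off-default values for the two dominant wobble classes; leaving
  # the minor classes at their defaults keeps the recovery identifiable
  planted <- default_class_coeffs()
  planted[c("gu", "ug")] <- 0.4
  tb_pl <- build_recognition_table(default_wobble_rules(), planted)
  w_pl <- tai_weights(tb_pl, lv)
  targets <- vapply(orfs, tai_of_sequence, 0, weights = w_pl)

  opt <- optimize_interaction_coefficients(tb, lv, orfs, targets)
  expect_equal(attr(opt, "objective"), 1.0, tolerance = 1e-9)
  # the dominant wobble classes must land on the planted grid value
  cf <- attr(opt, "coefficients")
  expect_equal(unname(cf["gu"]), 0.4, tolerance = 0.051)
  expect_equal(unname(cf["ug"]), 0.4, tolerance = 0.051)

  expect_error(
    optimize_interaction_coefficients(tb, lv, orfs, rep(1, length(orfs))),
    "constant")
})

test_that("optimizer never beats the exhaustive grid (brute-force oracle)", {
  # single free class: coordinate search must equal the grid argmax
  rules <- data.frame(
    codon = c("GGC", "GGU", "GGA", "GGG", "GGG"),
    trna_id = c("tG", "tG", "tU", "tU", "tC"),
    class = c("watson_crick", "wob", "watson_crick", "wob", "watson_crick"))
  lv <- c(tG = 40, tU = 20, tC = 10)
  set.seed(11)
  orfs <- lapply(1:15, function(i)
    random_orf(30, codons = c("GGC", "GGU", "GGA", "GGG")))
  target <- seq_along(orfs) + rnorm(15, 0, 2)

  grid <- seq(0.05, 1, by = 0.05)
  brute <- vapply(grid, function(g) {
    tb <- build_recognition_table(
      rules, c(watson_crick = 1, wob = g), partial = TRUE)
    tai <- vapply(orfs, tai_of_sequence, 0,
                  weights = tai_weights(tb, lv))
    cor(tai, target, method = "spearman")
  }, 0)

  tb0 <- build_recognition_table(rules, c(watson_crick = 1, wob = 0.5),
                                 partial = TRUE)
  opt <- optimize_interaction_coefficients(tb0, lv, orfs, target,
                                           grid = grid)
  expect_lte(attr(opt, "objective"), max(brute) + 1e-12)
  expect_equal(attr(opt, "objective"), max(brute), tolerance = 1e-12)
})

test_that("genetic-code utilities", {
  expect_length(sense_codons(), 61L)
  expect_length(stop_codons(), 3L)
  expect_equal(translate_codons(c("AUG", "UGG", "UAA")), "MW*")
  expect_equal(codons_of("atgTGGtaa"), c("AUG", "UGG", "UAA"))
  expect_equal(strip_stop(c("AUG", "UAA")), "AUG")
  expect_error(codons_of("AUGC"), "multiple of 3")
})
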