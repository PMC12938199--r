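test_that("hydropathy scale normalizes each property onto [0, 1]", {
  sc <- hydropathy_scale()
  expect_identical(rownames(sc), AA_ALPHABET)
  expect_equal(unname(apply(sc, 2, range)), matrix(c(0, 1, 0, 1), 2))
  raw <- hydropathy_scale(normalize = FALSE)
  expect_equal(unname(sc[, 1]),
               unname((raw[, 1] - min(raw[, 1])) / diff(range(raw[, 1]))))
})

test_that("APAAC of a zero-hydropathy homopolymer is pure composition", {
  v <- apaac(strrep("A", 50), scale = zero_at_A_scale(), lambda = 10)
  expect_equal(unname(v[1]), 1)           # f_A / (1 + 0)
  expect_equal(unname(v[-1]), rep(0, 19 + 20))
})

test_that("APAAC components always sum to one", {
  for (i in 1:100) {
    v <- apaac(random_protein(40 + (i * 11) %% 300, i), lambda = 30)
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
})

test_that("APAAC matches the term-by-term scalar oracle", {
  sc <- hydropathy_scale()
  for (i in 1:10) {
    s <- random_protein(40, 1000 + i)
    expect_equal(unname(apaac(s, sc, 0.5, 2L)),
                 oracle_apaac(s, sc, 0.5, 2), tolerance = 1e-12)
    s2 <- random_protein(90, 2000 + i)
    expect_equal(unname(apaac(s2, sc, 0.5, 30L)),
                 oracle_apaac(s2, sc, 0.5, 30), tolerance = 1e-12)
  }
})

test_that("APAAC rejects sequences not longer than lambda", {
  expect_error(apaac(random_protein(30, 1), lambda = 30), "L = 30")
})

test_that("segment split covers the sequence with floor(L/4) cut points", {
  s10 <- random_protein(10, 5)
  segs <- split_segments(s10)
  expect_equal(nchar(segs), c(2, 2, 2, 4))
  expect_identical(paste(segs, collapse = ""), s10)

  s8 <- random_protein(8, 6)
  expect_equal(nchar(split_segments(s8)), rep(2, 4))
  expect_identical(paste(split_segments(s8), collapse = ""), s8)

  expect_error(split_segments("ACD"), "L = 3")
})

test_that("interval statistics match hand-worked cases", {
  v <- interval_stats("AAAA")
  expect_equal(unname(v[c("A_A", "B_A", "C_A", "D_A")]), c(1, 1, 1, 1))
  expect_true(all(v[!grepl("_A$", names(v))] == 0))

  v <- interval_stats("ACCC")      # q_A = 1 at position 1: g = [4 - 1]
  expect_equal(unname(v[c("A_A", "B_A", "C_A", "D_A")]), c(3, 3, 3, 1 / 4))
  expect_equal(unname(v[c("A_C", "B_C", "C_C", "D_C")]), c(1, 1, 1, 3 / 4))
  expect_true(all(v[grepl("_[DEFGHIKLMNPQRSTVWY]$", names(v))] == 0))
})

test_that("interval statistics agree with the brute-force oracle", {
  for (i in 1:200) {
    seg <- random_protein(3 + (i * 7) %% 60, 3000 + i)
    expect_equal(unname(interval_stats(seg)), oracle_interval_stats(seg))
  }
})

test_that("segment features have the residue-major layout and unit D sums", {
  s <- random_protein(123, 9)
  v2 <- segment_features(s)
  expect_length(v2, 320)
  for (k in 1:4) {
    d_k <- v2[grepl(paste0("^D_.*,", k, "$"), names(v2))]
    expect_equal(sum(d_k), 1, tolerance = 1e-12)
  }
  # a homopolymer with equal segment lengths gives identical segments
  v2h <- segment_features(strrep("A", 8))
  expect_equal(unname(v2h[grepl("^A_A", names(v2h))]), rep(1, 4))
  expect_equal(v2h[1:4], v2h[5:8], ignore_attr = TRUE)
})

test_that("sigmoid PSSM normalization is elementwise and symmetric", {
  expect_equal(normalize_pssm(matrix(0, 2, 20))[1, 1], 0.5)
  m <- matrix(rnorm(60), 3, 20)
  expect_equal(normalize_pssm(m) + normalize_pssm(-m),
               matrix(1, 3, 20), ignore_attr = TRUE)
  expect_equal(unclass(normalize_pssm(m)), 1 / (1 + exp(-m)), ignore_attr = TRUE)
})

test_that("evolution features match hand-worked and oracle values", {
  # constant matrix: all deviations vanish
  cm <- matrix(2, 10, 20)
  colnames(cm) <- AA_ALPHABET
  v3 <- evolution_features(cm)
  expect_equal(unname(v3[1:60]), rep(0, 60))
  expect_equal(unname(v3[61:80]), rep(1 / (1 + exp(-2)), 20))

  # L = 2, theta = 1, single-column hand check
  m2 <- matrix(c(1, -1), 2, 20)
  colnames(m2) <- AA_ALPHABET
  a <- 1 / (1 + exp(-c(1, -1)))
  abar <- mean(a)
  v3 <- evolution_features(m2, thetas = 1L)
  expect_equal(unname(v3[1]), (a[1] - abar) * (a[2] - abar))

  prot <- tiny_protein_inputs()
  ps <- prot$pssms[[3]]
  expect_length(evolution_features(ps), 80)
  expect_equal(unname(evolution_features(ps)),
               unname(oracle_evolution(pssm_in_alphabet_order(ps))))
})

test_that("evolution features are column-equivariant and well-behaved", {
  prot <- tiny_protein_inputs()
  ps <- pssm_in_alphabet_order(prot$pssms[[4]])
  v3 <- evolution_features(ps)
  expect_true(all(is.finite(v3)))
  expect_true(all(v3[61:80] > 0 & v3[61:80] < 1))

  set.seed(77)
  perm <- sample(20)
  shuffled <- ps[, perm]
  colnames(shuffled) <- NULL          # prevent automatic reordering
  v3p <- evolution_features(shuffled)
  expect_equal(unname(v3p), unname(v3[c(perm, perm + 20, perm + 40, perm + 60)]))

  expect_error(evolution_features(matrix(0, 3, 20), thetas = 3), "L > max")
})
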