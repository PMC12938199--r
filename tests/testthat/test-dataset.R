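loc_fixture <- function(n = 12) {
  ids <- sprintf("L%02d", 1:n)
  seqs <- stats::setNames(vapply(1:n, function(i)
    random_protein(55, 6000 + i), character(1)), ids)
  comp <- rep(c("nucleus", "membrane", "cytoplasm"), length.out = n)
  list(proteins = seqs, loc = stats::setNames(as.list(comp), ids))
}

test_that("length filtering keeps the 50-residue boundary inclusive", {
  seqs <- c(a = strrep("A", 49), b = strrep("A", 50), c = strrep("A", 51))
  expect_identical(names(filter_by_length(seqs)), c("b", "c"))
  expect_length(filter_by_length(character(0)), 0)
  expect_identical(filter_by_length(seqs, 0), seqs)
})

test_that("negative sampling pairs only disjoint compartments, deterministically", {
  fx <- loc_fixture()
  neg <- make_negatives(fx$proteins, fx$loc, 20, seed = 4)
  expect_equal(nrow(neg), 20)
  expect_true(all(neg$label == 0L))
  same_comp <- mapply(function(a, b) any(unlist(fx$loc[[a]]) %in% unlist(fx$loc[[b]])),
                      neg$id_a, neg$id_b)
  expect_false(any(same_comp))
  expect_identical(make_negatives(fx$proteins, fx$loc, 20, seed = 4), neg)
  expect_false(identical(make_negatives(fx$proteins, fx$loc, 20, seed = 5), neg))
  expect_error(make_negatives(fx$proteins, fx$loc, 1e6, seed = 1),
               "eligible")
})

test_that("negative sampling excludes known positives and prior draws", {
  fx <- loc_fixture()
  pos <- data.frame(id_a = "L01", id_b = "L02", label = 1L)
  neg1 <- make_negatives(fx$proteins, fx$loc, 15, seed = 2, positives = pos)
  expect_false(any(paste(neg1$id_a, neg1$id_b) == "L01 L02"))
  neg2 <- make_negatives(fx$proteins, fx$loc, 15, seed = 3, positives = pos,
                         exclude = neg1)
  k1 <- paste(pmin(neg1$id_a, neg1$id_b), pmax(neg1$id_a, neg1$id_b))
  k2 <- paste(pmin(neg2$id_a, neg2$id_b), pmax(neg2$id_a, neg2$id_b))
  expect_length(intersect(k1, k2), 0)
})

test_that("the nucleus/cytoplasm curation rule drops other multi-localized proteins", {
  fx <- loc_fixture()
  fx$loc[["L01"]] <- c("nucleus", "membrane")      # dropped under the rule
  fx$loc[["L02"]] <- c("nucleus", "cytoplasm")     # kept
  neg <- make_negatives(fx$proteins, fx$loc, 10, seed = 8,
                        nuclear_cytoplasm_rule = TRUE)
  expect_false("L01" %in% c(neg$id_a, neg$id_b))
})

test_that("3:1:1 split partitions pairs with validation-first remainders", {
  pairs <- data.frame(id_a = paste0("a", 1:10), id_b = paste0("b", 1:10),
                      label = 1L)
  sp <- split_positives(pairs, seed = 1)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 6L, validation = 2L, test = 2L))
  expect_identical(split_positives(pairs, seed = 1), sp)

  for (n in 5:25) {
    pn <- data.frame(id_a = paste0("a", 1:n), id_b = paste0("b", 1:n),
                     label = 1L)
    spn <- split_positives(pn, seed = n)
    sizes <- vapply(spn, nrow, integer(1))
    expect_equal(sum(sizes), n)
    expect_equal(unname(sizes["train"]), floor(n * 3 / 5))
    key <- function(df) paste(df$id_a, df$id_b)
    all_keys <- unlist(lapply(spn, key))
    expect_setequal(all_keys, key(pn))
    expect_equal(anyDuplicated(all_keys), 0L)
  }
  expect_error(split_positives(pairs[1:4, ]), "at least 5")
})

make_split_fixture <- function(seed = 13) {
  cfg <- fixture_config(n_proteins = 40L, positive_rate = 0.1, seed = seed)
  prot <- gen_proteins(cfg)
  net <- gen_interactions(prot, cfg)
  split <- make_split(net$positives, prot, net$localizations, seed = seed)
  list(split = split, net = net, proteins = prot)
}

test_that("full splits keep negatives disjoint from positives and each other", {
  fx <- make_split_fixture()
  split <- fx$split
  key <- function(df) paste(pmin(df$id_a, df$id_b), pmax(df$id_a, df$id_b))
  pos_keys <- key(fx$net$positives)
  neg_keys <- c(key(split$train$neg), key(split$validation$neg),
                key(split$test$neg))
  expect_length(intersect(pos_keys, neg_keys), 0)
  expect_equal(anyDuplicated(neg_keys), 0L)
  expect_equal(nrow(split$validation$neg), nrow(split$validation$pos))
})

test_that("undersampled ensembles are balanced, seeded and distinct", {
  fx <- make_split_fixture()
  sets <- undersample_ensembles(fx$split, k = 5)
  expect_length(sets, 5)
  n_pos <- nrow(fx$split$train$pos)
  for (s in sets) {
    expect_equal(nrow(s), 2 * n_pos)
    expect_equal(sum(s$label == 1), n_pos)
    expect_equal(sum(s$label == 0), n_pos)
    expect_equal(anyDuplicated(paste(s$id_a, s$id_b, s$label)), 0L)
  }
  expect_identical(undersample_ensembles(fx$split, k = 5), sets)
  negs <- lapply(sets, function(s) sort(paste(s$id_a, s$id_b)[s$label == 0]))
  expect_gt(length(unique(negs)), 1)
})

test_that("imbalanced test variants draw ratio-times negatives", {
  fx <- make_split_fixture()
  n_pos <- nrow(fx$split$test$pos)
  t1 <- make_imbalanced_test(fx$split, ratio = 1)
  expect_equal(nrow(t1), 2 * n_pos)
  t3 <- make_imbalanced_test(fx$split, ratio = 3)
  expect_equal(sum(t3$label == 0), 3 * n_pos)
  expect_identical(make_imbalanced_test(fx$split, ratio = 3), t3)
  expect_error(make_imbalanced_test(fx$split, ratio = 50), "insufficient")
})

test_that("the protein-disjoint test drops any pair touching a training protein", {
  fx <- make_split_fixture()
  nt <- suppressWarnings(protein_disjoint_test(fx$split))  # may be empty at this scale
  train_ids <- unique(c(fx$split$train$pos$id_a, fx$split$train$pos$id_b,
                        fx$split$train$neg$id_a, fx$split$train$neg$id_b))
  expect_false(any(nt$id_a %in% train_ids))
  expect_false(any(nt$id_b %in% train_ids))

  empty_train <- fx$split
  empty_train$train$pos <- empty_train$train$pos[0, ]
  empty_train$train$neg <- empty_train$train$neg[0, ]
  nt2 <- protein_disjoint_test(empty_train)
  expect_equal(nrow(nt2), nrow(fx$split$test$pos) + nrow(fx$split$test$neg))
})
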