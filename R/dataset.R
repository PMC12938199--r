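#' Filter proteins by minimum sequence length
#'
#' @param proteins Named character vector of sequences.
#' @param min_len Minimum retained length (inclusive; default 50).
#' @return The retained subset, order preserved.
#' @export
filter_by_length <- function(proteins, min_len = 50L) {
  proteins[nchar(proteins) >= min_len]
}

# Canonical unordered-pair key: lexicographically smaller id first.
pair_key <- function(id_a, id_b) {
  paste(pmin(id_a, id_b), pmax(id_a, id_b), sep = "\r")
}

#' Construct negative pairs by the subcellular-localization strategy
#'
#' Candidate pairs are unordered protein pairs whose compartment sets are
#' disjoint (proteins located in different compartments generally do not
#' interact); known positives and duplicates are excluded, and `n` pairs
#' are drawn uniformly without replacement. Proteins absent from the
#' localization table are excluded from candidacy.
#'
#' @param proteins Named character vector (names are the candidate ids).
#' @param localizations Named list of compartment vectors.
#' @param n Number of negative pairs to draw.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param positives Optional data frame of known positive pairs
#'   (`id_a`, `id_b`) to exclude.
#' @param exclude Optional additional pair table to exclude (e.g. negatives
#'   already assigned to another partition).
#' @param nuclear_cytoplasm_rule If `TRUE`, multi-compartment proteins are
#'   kept only when annotated to both the nucleus and the cytoplasm (the
#'   dataset-specific curation rule); off by default.
#' @return Data frame `id_a`, `id_b`, `label = 0`.
#' @export
make_negatives <- function(proteins, localizations, n, seed,
                           positives = NULL, exclude = NULL,
                           nuclear_cytoplasm_rule = FALSE) {
  ids <- intersect(names(proteins), names(localizations))
  loc <- localizations[ids]
  if (nuclear_cytoplasm_rule) {
    keep <- vapply(loc, function(cs) {
      length(cs) == 1L || all(c("nucleus", "cytoplasm") %in% cs)
    }, logical(1))
    ids <- ids[keep]
    loc <- loc[keep]
  }
  if (length(ids) < 2L) ppi_stop("fewer than 2 localized proteins")
  cmb <- utils::combn(length(ids), 2L)
  disjoint <- vapply(seq_len(ncol(cmb)), function(k) {
    !any(loc[[cmb[1, k]]] %in% loc[[cmb[2, k]]])
  }, logical(1))
  id_a <- ids[cmb[1, disjoint]]
  id_b <- ids[cmb[2, disjoint]]
  keys <- pair_key(id_a, id_b)
  drop <- duplicated(keys)
  if (!is.null(positives)) drop <- drop | keys %in% pair_key(positives$id_a, positives$id_b)
  if (!is.null(exclude) && nrow(exclude)) drop <- drop | keys %in% pair_key(exclude$id_a, exclude$id_b)
  id_a <- id_a[!drop]; id_b <- id_b[!drop]
  if (length(id_a) < n) {
    ppi_stop("only %d eligible negative pairs available (requested %d)",
             length(id_a), n)
  }
  sel <- with_seed(seed, sample.int(length(id_a), n))
  data.frame(id_a = id_a[sel], id_b = id_b[sel], label = 0L,
             stringsAsFactors = FALSE)
}

#' Split positive pairs into train / validation / test partitions
#'
#' Seeded shuffle followed by a contiguous cut at the given proportions.
#' On non-divisible counts the training partition receives the floor of
#' its share and the remainder is distributed one pair at a time starting
#' with the validation partition, then the test partition.
#'
#' @param pairs Data frame of positive pairs.
#' @param ratios Partition weights (default `c(3, 1, 1)`).
#' @param seed Integer seed.
#' @return List of three data frames: `train`, `validation`, `test`.
#' @export
split_positives <- function(pairs, ratios = c(3, 1, 1), seed = 1L) {
  n <- nrow(pairs)
  if (n < 5L) ppi_stop("need at least 5 positive pairs to split (got %d)", n)
  sizes <- floor(n * ratios / sum(ratios))
  extra <- n - sum(sizes)
  if (extra > 0) {
    recv <- rep(c(2L, 3L), length.out = extra)  # validation first, then test
    for (r in recv) sizes[r] <- sizes[r] + 1L
  }
  ord <- with_seed(seed, sample.int(n))
  cuts <- cumsum(sizes)
  list(train = pairs[ord[seq_len(cuts[1])], , drop = FALSE],
       validation = pairs[ord[(cuts[1] + 1L):cuts[2]], , drop = FALSE],
       test = pairs[ord[(cuts[2] + 1L):cuts[3]], , drop = FALSE])
}

#' Build a full dataset split with localization-based negatives
#'
#' Positives are split 3:1:1; each partition then receives its own
#' negative table drawn by [make_negatives()], with negatives disjoint
#' across partitions. The training partition gets `neg_ratio["train"]`
#' negatives per positive (the excess pool feeding the undersampling
#' ensemble), the validation partition a balanced set by default, and the
#' test partition a larger pool so imbalanced test variants can be drawn.
#'
#' @param positives Positive pair table.
#' @param proteins Named character vector of sequences.
#' @param localizations Named list of compartment vectors.
#' @param seed Master seed; partition draws use derived sub-seeds.
#' @param ratios Positive split weights.
#' @param neg_ratio Named negatives-per-positive multipliers.
#' @return List of class `"ppi_split"`: partitions `train`, `validation`,
#'   `test`, each holding `pos` and `neg` pair tables, plus the seed.
#' @export
make_split <- function(positives, proteins, localizations, seed = 1L,
                       ratios = c(3, 1, 1),
                       neg_ratio = c(train = 3, validation = 1, test = 3)) {
  parts <- split_positives(positives, ratios, derive_seed(seed, 11L))
  neg_sofar <- NULL
  out <- list()
  for (k in seq_along(parts)) {
    nm <- names(parts)[k]
    n_neg <- ceiling(nrow(parts[[k]]) * neg_ratio[[nm]])
    neg <- make_negatives(proteins, localizations, n_neg,
                          derive_seed(seed, 20L + k),
                          positives = positives, exclude = neg_sofar)
    neg_sofar <- rbind(neg_sofar, neg)
    out[[nm]] <- list(pos = parts[[k]], neg = neg)
  }
  structure(c(out, list(seed = seed)), class = "ppi_split")
}

#' Balanced training sets for the undersampling ensemble
#'
#' Draws `k` independent negative subsets of the training partition, each
#' the size of the positive set and drawn without replacement within a
#' set, and combines each with all training positives.
#'
#' @param split A `"ppi_split"` from [make_split()].
#' @param k Number of balanced sets (default 5).
#' @param seed Master seed; each draw uses a derived sub-seed.
#' @return List of `k` pair tables (positives + balanced negative draw).
#' @export
undersample_ensembles <- function(split, k = 5L, seed = split$seed) {
  pos <- split$train$pos
  neg <- split$train$neg
  if (nrow(neg) < nrow(pos)) {
    ppi_stop("training negatives (%d) fewer than positives (%d)",
             nrow(neg), nrow(pos))
  }
  lapply(seq_len(k), function(j) {
    sel <- with_seed(derive_seed(seed, 40L + j), sample.int(nrow(neg), nrow(pos)))
    rbind(pos, neg[sel, , drop = FALSE])
  })
}

#' Imbalanced test variant
#'
#' All test positives plus a seeded draw of `ratio` negatives per
#' positive.
#'
#' @param split A `"ppi_split"`.
#' @param ratio Negatives per positive (1 gives a balanced test set; the
#'   imbalanced variants use 5 and 10).
#' @param seed Integer seed.
#' @return Pair table.
#' @export
make_imbalanced_test <- function(split, ratio = 5, seed = split$seed) {
  pos <- split$test$pos
  neg <- split$test$neg
  need <- ceiling(nrow(pos) * ratio)
  if (nrow(neg) < need) {
    ppi_stop("test negatives (%d) insufficient for ratio %s (need %d)",
             nrow(neg), format(ratio), need)
  }
  sel <- with_seed(derive_seed(seed, 60L + round(ratio)), sample.int(nrow(neg), need))
  rbind(pos, neg[sel, , drop = FALSE])
}

#' Protein-disjoint test pairs
#'
#' Returns the test pairs (positives and negatives) in which neither
#' protein occurs in any training pair - the stricter "new-test"
#' evaluation that removes protein identity leakage across partitions.
#'
#' @param split A `"ppi_split"`.
#' @return Pair table (possibly empty, with a warning).
#' @export
protein_disjoint_test <- function(split) {
  train_ids <- unique(c(split$train$pos$id_a, split$train$pos$id_b,
                        split$train$neg$id_a, split$train$neg$id_b))
  test <- rbind(split$test$pos, split$test$neg)
  keep <- !(test$id_a %in% train_ids) & !(test$id_b %in% train_ids)
  out <- test[keep, , drop = FALSE]
  if (!nrow(out)) warning("protein-disjoint test set is empty")
  out
}
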