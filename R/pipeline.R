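#' Extract the 576-feature table for a protein set
#'
#' Computes [protein_feature_vector()] for every protein that has both a
#' coding sequence and a PSSM; proteins missing either are skipped with a
#' warning listing them.
#'
#' @param proteins Named character vector of protein sequences.
#' @param genes Named character vector of coding sequences.
#' @param pssms Named list of L x 20 score matrices.
#' @param ablate Optional feature families to zero (see
#'   [zero_families()]).
#' @param ... Passed to [protein_feature_vector()].
#' @return Numeric matrix (proteins x 576) with feature-name columns.
#' @export
extract_feature_table <- function(proteins, genes, pssms, ablate = NULL, ...) {
  ids <- names(proteins)
  missing_inputs <- ids[!(ids %in% names(genes)) | !(ids %in% names(pssms))]
  if (length(missing_inputs)) {
    warning("skipping proteins without CDS or PSSM: ",
            paste(missing_inputs, collapse = ", "))
    ids <- setdiff(ids, missing_inputs)
  }
  if (!length(ids)) ppi_stop("no proteins with complete inputs")
  rows <- lapply(ids, function(id)
    protein_feature_vector(proteins[[id]], genes[[id]], pssms[[id]], ...))
  tab <- do.call(rbind, rows)
  rownames(tab) <- ids
  if (!is.null(ablate)) tab <- zero_families(tab, ablate)
  tab
}

#' Build the 36 x 32 map stack for a pair table
#'
#' Each protein's 36 x 16 matrix is built once; every pair is the
#' horizontal concatenation of its two matrices, min-max normalized per
#' sample.
#'
#' @param features Feature table from [extract_feature_table()].
#' @param pairs Pair table (`id_a`, `id_b`, optional `label`).
#' @param layout Cell arrangement from [feature_layout()].
#' @return List with `x` (36 x 32 x n array), `y` (labels, `NA` when
#'   absent) and `pairs`.
#' @export
pair_maps <- function(features, pairs, layout = feature_layout()) {
  ids <- unique(c(pairs$id_a, pairs$id_b))
  missing_ids <- setdiff(ids, rownames(features))
  if (length(missing_ids)) {
    ppi_stop("pair table references proteins without features (first: %s)",
             missing_ids[1])
  }
  mats <- lapply(ids, function(id) build_matrix(features[id, ], layout))
  names(mats) <- ids
  x <- array(NA_real_, c(36L, 32L, nrow(pairs)))
  for (i in seq_len(nrow(pairs))) {
    x[, , i] <- build_pair_map(mats[[pairs$id_a[i]]], mats[[pairs$id_b[i]]])
  }
  y <- if ("label" %in% names(pairs)) pairs$label else rep(NA_integer_, nrow(pairs))
  list(x = x, y = y, pairs = pairs)
}

#' Maps and labels for a list of pair tables
#'
#' @param features Feature table.
#' @param tables List of pair tables (e.g. from
#'   [undersample_ensembles()]).
#' @param layout Cell arrangement.
#' @return List of `list(x, y, pairs)` entries.
#' @export
maps_for_tables <- function(features, tables, layout = feature_layout()) {
  lapply(tables, pair_maps, features = features, layout = layout)
}

#' Fit a per-feature min-max scaler on a feature table
#'
#' Records each feature's minimum and maximum over a reference protein set
#' (normally the proteins of the training partition). Applying the scaler
#' maps every feature onto a comparable \[0, 1\] scale before the maps are
#' assembled, which is what removes the raw scale differences between
#' feature families (positional variances reach the order of N^2/12 while
#' composition terms stay below one).
#'
#' @param features Feature table from [extract_feature_table()].
#' @return List of class `"feature_scaler"` with `min` and `range` per
#'   feature.
#' @export
feature_scaler <- function(features) {
  mins <- apply(features, 2L, min)
  maxs <- apply(features, 2L, max)
  structure(list(min = mins, range = maxs - mins), class = "feature_scaler")
}

#' Apply a per-feature min-max scaler
#'
#' Features constant in the reference set map to zero; values outside the
#' reference range extrapolate linearly (the later per-sample map
#' normalization keeps every map inside \[0, 1\]).
#'
#' @param features Feature table.
#' @param scaler A [feature_scaler()].
#' @return Scaled feature table of the same shape.
#' @export
scale_features <- function(features, scaler) {
  stopifnot(inherits(scaler, "feature_scaler"),
            identical(colnames(features), names(scaler$min)))
  rng <- ifelse(scaler$range == 0, 1, scaler$range)
  out <- sweep(sweep(features, 2L, scaler$min), 2L, rng, "/")
  out[, scaler$range == 0] <- 0
  out
}
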