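#' Full 576-value feature vector of one protein
#'
#' Concatenates the four feature families in the fixed order
#' V1 (APAAC, 80), V2 (segmented interval-distance statistics, 320),
#' V3 (PSSM evolutionary descriptors, 80), V4 (gene-sequence features, 96).
#' Names are prefixed with their family (`V1.`, `V2.`, ...) so that every
#' feature has a unique identity; the family index ranges are attached as
#' attribute `blocks`.
#'
#' @param residues Protein sequence.
#' @param cds Coding gene sequence for the same protein.
#' @param pssm L x 20 score matrix for the same protein (row count must
#'   equal the protein length).
#' @param scale,omega,lambda Passed to [apaac()].
#' @param thetas Passed to [evolution_features()].
#' @return Named numeric vector of length 576.
#' @export
protein_feature_vector <- function(residues, cds, pssm,
                                   scale = hydropathy_scale(),
                                   omega = 0.5, lambda = 30L, thetas = 1:3) {
  if (nrow(pssm) != nchar(residues)) {
    ppi_stop("PSSM has %d rows but the protein has %d residues",
             nrow(pssm), nchar(residues))
  }
  v1 <- apaac(residues, scale, omega, lambda)
  v2 <- segment_features(residues)
  v3 <- evolution_features(pssm, thetas)
  v4 <- gene_features(cds)
  out <- c(v1, v2, v3, v4)
  names(out) <- c(paste0("V1.", names(v1)), paste0("V2.", names(v2)),
                  paste0("V3.", names(v3)), paste0("V4.", names(v4)))
  attr(out, "blocks") <- list(
    V1 = seq_along(v1),
    V2 = length(v1) + seq_along(v2),
    V3 = length(v1) + length(v2) + seq_along(v3),
    V4 = length(v1) + length(v2) + length(v3) + seq_along(v4))
  out
}

#' Canonical 36 x 16 arrangement of the 576 features
#'
#' Returns the provenance map of the per-protein feature matrix: a 36 x 16
#' character matrix whose cell holds the name of the feature placed there.
#' Rows 1-20 hold V2 (one residue per row, its 16 statistics
#' `A,B,C,D x 4 segments`); rows 21-25 hold V1 (`v1..v80`, 16 per row);
#' rows 26-30 hold V3 filled row-major in the order `abar(20), phi1(20),
#' phi2(20), phi3(20)`; rows 31-36 hold V4 (circle and positional
#' statistics plus single/di-nucleotide frequencies on rows 31-32, the 64
#' trinucleotide frequencies on rows 33-36, ending `f_TTT`).
#'
#' @param lambda APAAC rank (80 V1 features requires the default 30).
#' @param thetas PSSM separations (default `1:3`).
#' @return 36 x 16 character matrix of feature names.
#' @export
feature_layout <- function(lambda = 30L, thetas = 1:3) {
  # per residue: segment-major blocks of A,B,C,D
  v2 <- unlist(lapply(AA_ALPHABET, function(m)
    paste0("V2.", paste0(rep(c("A_", "B_", "C_", "D_"), times = 4L), m, ",",
                         rep(1:4, each = 4L)))))
  v1 <- paste0("V1.", c(paste0("f_", AA_ALPHABET), paste0("tau_", seq_len(2L * lambda))))
  v3 <- paste0("V3.", c(paste0("abar_", AA_ALPHABET),
                        paste0("phi", rep(thetas, each = 20L), "_",
                               rep(AA_ALPHABET, length(thetas)))))
  v4 <- paste0("V4.", c("mu_x", "mu_y", "var_x", "var_y",
                        paste0("mu_", NT_ALPHABET), paste0("var_", NT_ALPHABET),
                        paste0("f_", all_kmers(1)), paste0("f_", all_kmers(2)),
                        paste0("f_", all_kmers(3))))
  ordered <- c(v2, v1, v3, v4)
  matrix(ordered, nrow = 36L, ncol = 16L, byrow = TRUE)
}

#' Arrange a feature vector into its 36 x 16 matrix
#'
#' @param fv 576-value vector from [protein_feature_vector()].
#' @param layout Provenance map from [feature_layout()] (or a rearranged
#'   one).
#' @return 36 x 16 numeric matrix with the layout attached as attribute
#'   `provenance`.
#' @export
build_matrix <- function(fv, layout = feature_layout()) {
  if (length(fv) != 576L) ppi_stop("expected a 576-value feature vector, got %d", length(fv))
  if (!all(layout %in% names(fv))) {
    ppi_stop("feature vector names do not match the layout (first missing: %s)",
             layout[which(!layout %in% names(fv))[1]])
  }
  m <- matrix(fv[as.vector(layout)], 36L, 16L)
  attr(m, "provenance") <- layout
  m
}

#' Recover the ordered feature vector from a feature matrix
#'
#' Inverse of [build_matrix()]: uses the provenance map to return the 576
#' features in canonical V1, V2, V3, V4 order.
#'
#' @param m Matrix from [build_matrix()].
#' @return Named numeric vector of length 576.
#' @export
flatten_matrix <- function(m) {
  layout <- attr(m, "provenance")
  if (is.null(layout)) ppi_stop("matrix has no provenance map")
  v <- stats::setNames(as.vector(m), as.vector(layout))
  v[canonical_feature_names()]
}

# The 576 feature names in canonical vector order (V1, V2, V3, V4, with
# V3 listed phi1, phi2, phi3, abar as in the feature-vector contract).
canonical_feature_names <- function(lambda = 30L, thetas = 1:3) {
  lay <- feature_layout(lambda, thetas)
  rm_names <- as.vector(t(lay))
  c(grep("^V1\\.", rm_names, value = TRUE),
    grep("^V2\\.", rm_names, value = TRUE),
    paste0("V3.", c(paste0("phi", rep(thetas, each = 20L), "_",
                           rep(AA_ALPHABET, length(thetas))),
                    paste0("abar_", AA_ALPHABET))),
    grep("^V4\\.", rm_names, value = TRUE))
}

#' Min-max normalize a matrix to \[0, 1\]
#'
#' A constant matrix maps to all zeros rather than dividing by zero.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape with entries in \[0, 1\].
#' @export
minmax_normalize <- function(m) {
  r <- range(m)
  if (r[1] == r[2]) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

#' Build the 36 x 32 grayscale map of a protein pair
#'
#' Horizontally concatenates the two per-protein feature matrices and
#' min-max normalizes the result over the entire 36 x 32 matrix, so each
#' sample spans exactly \[0, 1\] (per-sample normalization; the two
#' proteins share one scale within a sample).
#'
#' @param m_a,m_b 36 x 16 matrices from [build_matrix()].
#' @param normalize Apply the per-sample min-max step (default `TRUE`).
#' @return 36 x 32 numeric matrix.
#' @export
build_pair_map <- function(m_a, m_b, normalize = TRUE) {
  stopifnot(all(dim(m_a) == c(36L, 16L)), all(dim(m_b) == c(36L, 16L)))
  m <- cbind(unclass(m_a), unclass(m_b))
  attr(m, "provenance") <- NULL
  if (normalize) m <- minmax_normalize(m)
  m
}

#' Export a pair map as an 8-bit grayscale PNG
#'
#' Pixel brightness is `round(255 * value)`; the image is 32 pixels wide
#' and 36 tall.
#'
#' @param map 36 x 32 matrix with values in \[0, 1\].
#' @param path Output PNG path.
#' @export
export_png <- function(map, path) {
  stopifnot(all(dim(map) == c(36L, 32L)))
  png::writePNG(pmin(pmax(map, 0), 1), target = path)
  invisible(path)
}

#' Rearrange the cells of a feature matrix
#'
#' Applies a bijection over the 576 cells (enumerated row-major), updating
#' the provenance map. Used to reproduce the arrangement-invariance
#' experiments: model accuracy is insensitive to the within-map feature
#' arrangement.
#'
#' @param m Matrix from [build_matrix()].
#' @param permutation Integer permutation of `1:576` (cell `i` of the
#'   output, row-major, takes cell `permutation[i]` of the input), or
#'   `"identity"`.
#' @return Rearranged matrix with updated provenance.
#' @export
rearrange <- function(m, permutation = "identity") {
  if (identical(permutation, "identity")) permutation <- seq_len(576L)
  if (length(permutation) != 576L || !setequal(permutation, seq_len(576L))) {
    ppi_stop("permutation must be a bijection over the 576 cells")
  }
  layout <- attr(m, "provenance")
  rm_vals <- as.vector(t(m))[permutation]          # row-major
  out <- matrix(rm_vals, 36L, 16L, byrow = TRUE)
  if (!is.null(layout)) {
    attr(out, "provenance") <- matrix(as.vector(t(layout))[permutation],
                                      36L, 16L, byrow = TRUE)
  }
  out
}

#' Random cell rearrangement
#'
#' @param seed Integer seed.
#' @return Integer permutation of `1:576` for [rearrange()].
#' @export
random_rearrangement <- function(seed) {
  with_seed(seed, sample.int(576L))
}

# Evaluate `expr` under a temporary RNG state so library code never
# disturbs the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Zero one or more feature families (ablation)
#'
#' Sets every feature of the selected families to zero, reproducing the
#' feature-ablation experiments. Works on a single feature vector or on a
#' feature table (rows = proteins).
#'
#' @param x 576-value vector from [protein_feature_vector()], or a matrix
#'   with 576 named columns.
#' @param families Subset of `c("V1", "V2", "V3", "V4")`.
#' @return Object of the same shape with the selected blocks zeroed.
#' @export
zero_families <- function(x, families) {
  bad <- setdiff(families, c("V1", "V2", "V3", "V4"))
  if (length(bad)) ppi_stop("unknown feature family '%s'", bad[1])
  nm <- if (is.matrix(x)) colnames(x) else names(x)
  mask <- grepl(paste0("^(", paste(families, collapse = "|"), ")\\."), nm)
  if (is.matrix(x)) x[, mask] <- 0 else x[mask] <- 0
  x
}
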