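# Hydropathy scale: the two physicochemical properties driving APAAC.
# Values are the canonical pseudo-amino-acid-composition inputs
# (Tanford-style hydrophobicity, Hopp-Woods hydrophilicity); both are
# min-max scaled to [0, 1] across the 20 residues before use.
.HYDROPHOBICITY <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
  G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
  M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
  S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26)

.HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
  G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
  M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
  S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)

minmax_scale <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Hydropathy scale used by APAAC
#'
#' Returns the per-residue hydrophobicity and hydrophilicity values, min-max
#' normalized so each property spans exactly \[0, 1\] across the 20
#' residues. An alternative scale can be loaded from a tab-separated file
#' (residue, hydrophobicity, hydrophilicity) with `path`.
#'
#' @param path Optional three-column tab-separated scale file.
#' @param normalize Min-max scale each property (default `TRUE`).
#' @return 20 x 2 matrix, rows in [AA_ALPHABET] order, columns
#'   `hydrophobicity` and `hydrophilicity`.
#' @export
hydropathy_scale <- function(path = NULL, normalize = TRUE) {
  if (is.null(path)) {
    m <- cbind(hydrophobicity = .HYDROPHOBICITY[AA_ALPHABET],
               hydrophilicity = .HYDROPHILICITY[AA_ALPHABET])
  } else {
    df <- utils::read.delim(path, header = FALSE, col.names = c("aa", "hb", "hl"))
    if (!all(AA_ALPHABET %in% df$aa)) ppi_stop("scale file must cover all 20 residues")
    m <- cbind(hydrophobicity = df$hb[match(AA_ALPHABET, df$aa)],
               hydrophilicity = df$hl[match(AA_ALPHABET, df$aa)])
  }
  rownames(m) <- AA_ALPHABET
  if (normalize) m <- apply(m, 2, minmax_scale)
  m
}

seq_to_chars <- function(seq) strsplit(seq, "")[[1]]

#' Amphiphilic pseudo amino acid composition (V1)
#'
#' The 20 residue-composition terms plus `2 * lambda` sequence-order
#' correlation factors: for each rank `d = 1..lambda`, the mean product of
#' normalized hydrophobicity values at separation `d` (factor `2d - 1`) and
#' the analogous hydrophilicity factor (`2d`). Components are jointly
#' normalized so the whole vector sums to one:
#' `v_t = f_m / (1 + w * sum(tau))` for the composition block and
#' `v_t = w * tau_(t-20) / (1 + w * sum(tau))` for the correlation block.
#'
#' @param seq Protein sequence (string over the 20-letter alphabet).
#' @param scale Hydropathy scale matrix from [hydropathy_scale()].
#' @param omega Weight factor for the correlation block (default 0.5).
#' @param lambda Maximum correlation rank (default 30); must be < sequence
#'   length.
#' @return Named numeric vector of length `20 + 2 * lambda`.
#' @export
apaac <- function(seq, scale = hydropathy_scale(), omega = 0.5, lambda = 30L) {
  chars <- seq_to_chars(seq)
  L <- length(chars)
  if (L <= lambda) {
    ppi_stop("APAAC requires sequence length L > lambda (L = %d, lambda = %d)", L, lambda)
  }
  phi1 <- unname(scale[chars, "hydrophobicity"])
  phi2 <- unname(scale[chars, "hydrophilicity"])
  f <- tabulate(match(chars, AA_ALPHABET), nbins = 20L) / L
  tau <- numeric(2L * lambda)
  for (d in seq_len(lambda)) {
    idx <- seq_len(L - d)
    tau[2L * d - 1L] <- sum(phi1[idx] * phi1[idx + d]) / (L - d)
    tau[2L * d]      <- sum(phi2[idx] * phi2[idx + d]) / (L - d)
  }
  denom <- 1 + omega * sum(tau)
  v <- c(f / denom, omega * tau / denom)
  names(v) <- c(paste0("f_", AA_ALPHABET), paste0("tau_", seq_len(2L * lambda)))
  v
}

#' Split a protein sequence into four consecutive segments
#'
#' With `l = floor(L / 4)`, the segments cover positions `1..l`,
#' `l+1..2l`, `2l+1..3l`, `3l+1..L`; their concatenation reproduces the
#' input. The final segment absorbs the remainder.
#'
#' @param seq Protein sequence with at least 4 residues.
#' @return Character vector of the 4 segment strings.
#' @export
split_segments <- function(seq) {
  L <- nchar(seq)
  if (L < 4L) ppi_stop("segment split requires L >= 4 (got L = %d)", L)
  l <- L %/% 4L
  c(substr(seq, 1L, l),
    substr(seq, l + 1L, 2L * l),
    substr(seq, 2L * l + 1L, 3L * l),
    substr(seq, 3L * l + 1L, L))
}

#' Interval-distance statistics of one segment
#'
#' For each residue type `m`, the occurrence positions (1-based within the
#' segment) define the same-type interval-distance sequence `g_m`: the gaps
#' between consecutive occurrences when `m` occurs more than once, the
#' single value `s - alpha_1` (distance from the sole occurrence to the
#' segment end) when it occurs once, and `0` when absent. Four statistics
#' are taken per residue: mean `A_m`, minimum `B_m`, maximum `C_m`, and the
#' frequency `D_m` (`q/s` for `q > 1`, `1/s` for `q = 1`, `0` for `q = 0`).
#'
#' @param segment Segment string of length `s >= 1`.
#' @return Named numeric vector of 80 values, grouped per residue in
#'   [AA_ALPHABET] order as `A_m, B_m, C_m, D_m`.
#' @export
interval_stats <- function(segment) {
  s <- nchar(segment)
  if (s < 1L) ppi_stop("interval_stats requires a non-empty segment")
  chars <- seq_to_chars(segment)
  out <- numeric(80L)
  names(out) <- paste0(rep(c("A_", "B_", "C_", "D_"), times = 20L),
                       rep(AA_ALPHABET, each = 4L))
  for (j in seq_along(AA_ALPHABET)) {
    alpha <- which(chars == AA_ALPHABET[j])
    q <- length(alpha)
    if (q == 0L) next
    g <- if (q > 1L) diff(alpha) else s - alpha[1L]
    base <- (j - 1L) * 4L
    out[base + 1L] <- mean(g)
    out[base + 2L] <- min(g)
    out[base + 3L] <- max(g)
    out[base + 4L] <- q / s
  }
  out
}

#' Segmented interval-distance features (V2)
#'
#' Applies [interval_stats()] to the four segments of [split_segments()]
#' and arranges the 320 values residue-major: for each residue `m` in
#' [AA_ALPHABET] order, the 16 values
#' `A_{m,1}, B_{m,1}, C_{m,1}, D_{m,1}, ..., A_{m,4}, ..., D_{m,4}`.
#' This ordering makes row `m` of the per-protein feature matrix exactly
#' that residue's 16 statistics.
#'
#' @param seq Protein sequence with at least 4 residues.
#' @return Named numeric vector of length 320.
#' @export
segment_features <- function(seq) {
  per_seg <- lapply(split_segments(seq), interval_stats)   # each 80, per-residue ABCD
  out <- numeric(320L)
  nm <- character(320L)
  for (j in seq_along(AA_ALPHABET)) {
    for (k in 1:4) {
      src <- (j - 1L) * 4L + 1:4
      dst <- (j - 1L) * 16L + (k - 1L) * 4L + 1:4
      out[dst] <- per_seg[[k]][src]
      nm[dst] <- paste0(c("A_", "B_", "C_", "D_"), AA_ALPHABET[j], ",", k)
    }
  }
  stats::setNames(out, nm)
}

#' Sigmoid normalization of a PSSM
#'
#' Maps each raw log-odds score through `1 / (1 + exp(-a))`, removing the
#' scale differences between positions before the evolutionary descriptors
#' are computed.
#'
#' @param pssm L x 20 score matrix.
#' @return Matrix of the same shape with entries in (0, 1).
#' @export
normalize_pssm <- function(pssm) {
  out <- 1 / (1 + exp(-unclass(pssm)))
  attr(out, "protein_id") <- attr(pssm, "protein_id")
  out
}

#' PSSM evolutionary conservation features (V3)
#'
#' On the sigmoid-normalized matrix, the column means `abar_w` summarize
#' per-residue conservation, and for each separation `theta` the interval
#' deviation product factor
#' `delta^theta_{i,w} = (a*_{i,w} - abar_w) * (a*_{i+theta,w} - abar_w)`
#' is averaged over `i = 1..L-theta` to give `Z^theta_w` (reported as
#' `phi^theta_w`), quantifying the co-evolution of positions `theta` apart.
#'
#' @param pssm L x 20 score matrix; columns are reordered to
#'   [AA_ALPHABET] when residue `colnames` are present.
#' @param thetas Integer separations (default `1:3`).
#' @param normalize Apply the sigmoid normalization first (default `TRUE`);
#'   set `FALSE` to evaluate the descriptors on raw scores.
#' @return Named numeric vector of length `20 * (length(thetas) + 1)`:
#'   `phi^1(20), phi^2(20), phi^3(20), abar(20)`.
#' @export
evolution_features <- function(pssm, thetas = 1:3, normalize = TRUE) {
  if (!is.null(colnames(pssm)) && all(AA_ALPHABET %in% colnames(pssm))) {
    pssm <- pssm_in_alphabet_order(pssm)
  }
  a <- unclass(pssm)
  L <- nrow(a)
  if (L <= max(thetas)) {
    ppi_stop("evolution features require L > max(theta) (L = %d, max theta = %d)",
             L, max(thetas))
  }
  if (normalize) a <- 1 / (1 + exp(-a))
  abar <- colMeans(a)
  dev <- sweep(a, 2L, abar)
  z <- vapply(thetas, function(th) {
    colSums(dev[seq_len(L - th), , drop = FALSE] *
            dev[seq_len(L - th) + th, , drop = FALSE]) / (L - th)
  }, numeric(20L))
  out <- c(as.vector(z), abar)
  names(out) <- c(paste0("phi", rep(thetas, each = 20L), "_", rep(AA_ALPHABET, length(thetas))),
                  paste0("abar_", AA_ALPHABET))
  out
}
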