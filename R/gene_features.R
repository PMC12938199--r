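#' k-mer frequencies of a coding sequence
#'
#' Overlapping single-, di- and tri-nucleotide window counts divided by the
#' number of windows (`N`, `N - 1`, `N - 2`), k-mers enumerated in
#' lexicographic A<C<G<T order. Each k-block sums to one.
#'
#' @param seq Nucleotide sequence (ACGT) with `N >= 3`.
#' @return Named numeric vector of length 84 (4 + 16 + 64).
#' @export
kmer_frequencies <- function(seq) {
  N <- nchar(seq)
  if (N < 3L) ppi_stop("k-mer frequencies require N >= 3 (got N = %d)", N)
  out <- numeric(0)
  for (k in 1:3) {
    kmers <- all_kmers(k)
    starts <- seq_len(N - k + 1L)
    words <- substring(seq, starts, starts + k - 1L)
    counts <- table(factor(words, levels = kmers))
    out <- c(out, stats::setNames(as.numeric(counts) / (N - k + 1L),
                                  paste0("f_", kmers)))
  }
  out
}

all_kmers <- function(k) {
  sort(do.call(paste0, expand.grid(rep(list(NT_ALPHABET), k),
                                   stringsAsFactors = FALSE)))
}

#' Positional statistics of each nucleotide
#'
#' For each nucleotide (A, C, G, T order) present in the sequence, the mean
#' and population variance of its 1-based occurrence positions; both are 0
#' for an absent nucleotide.
#'
#' @param seq Nucleotide sequence.
#' @return Named numeric vector of length 8: `mu_A..mu_T`, then
#'   `var_A..var_T`.
#' @export
position_stats <- function(seq) {
  chars <- seq_to_chars(seq)
  mu <- v <- stats::setNames(numeric(4L), NT_ALPHABET)
  for (e in NT_ALPHABET) {
    beta <- which(chars == e)
    if (length(beta)) {
      mu[e] <- mean(beta)
      v[e] <- mean((beta - mu[e])^2)
    }
  }
  c(stats::setNames(mu, paste0("mu_", NT_ALPHABET)),
    stats::setNames(v, paste0("var_", NT_ALPHABET)))
}

#' Map a coding sequence onto the unit circle
#'
#' Nucleotide `e` at position `r`, being the `b_e^r`-th occurrence of `e`
#' (cumulative count inclusive of `r`) out of `b_e` total, maps to the
#' angle `offset(e) + (pi/2) * b_e^r / (b_e + 1)` with quadrant offsets
#' 0, pi/2, pi, 3*pi/2 for A, C, G, T. Every point lies on the unit circle
#' strictly inside its nucleotide's quadrant.
#'
#' @param seq Nucleotide sequence.
#' @return Data frame with columns `position`, `nucleotide`, `x`, `y`.
#' @export
circle_map <- function(seq) {
  chars <- seq_to_chars(seq)
  N <- length(chars)
  if (N < 1L) ppi_stop("circle_map requires a non-empty sequence")
  offsets <- stats::setNames(c(0, pi / 2, pi, 3 * pi / 2), NT_ALPHABET)
  idx <- match(chars, NT_ALPHABET)
  total <- tabulate(idx, nbins = 4L)
  cum <- stats::ave(seq_len(N), idx, FUN = seq_along)  # b_e^r, inclusive
  ang <- offsets[idx] + (pi / 2) * cum / (total[idx] + 1)
  data.frame(position = seq_len(N), nucleotide = chars,
             x = cos(ang), y = sin(ang), row.names = NULL)
}

#' Summary statistics of the unit-circle mapping
#'
#' @param points Data frame from [circle_map()].
#' @return Named numeric vector `mu_x`, `mu_y`, `var_x`, `var_y` (means and
#'   population variances over all mapped points).
#' @export
circle_stats <- function(points) {
  if (!nrow(points)) ppi_stop("circle_stats requires at least one mapped point")
  c(mu_x = mean(points$x), mu_y = mean(points$y),
    var_x = mean((points$x - mean(points$x))^2),
    var_y = mean((points$y - mean(points$y))^2))
}

#' Gene-sequence features (V4)
#'
#' Concatenation of the unit-circle statistics (4), the per-nucleotide
#' positional means and variances (8), and the k-mer frequencies (84), in
#' the fixed order `mu_x, mu_y, var_x, var_y, mu_A..mu_T, var_A..var_T,
#' f_A, ..., f_TTT`.
#'
#' @param seq Coding sequence (ACGT) with `N >= 3`.
#' @return Named numeric vector of length 96.
#' @export
gene_features <- function(seq) {
  c(circle_stats(circle_map(seq)), position_stats(seq), kmer_frequencies(seq))
}
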