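#' Amino acid and nucleotide alphabets
#'
#' `AA_ALPHABET` is the fixed 20-letter residue listing (alphabetical) that
#' orders every residue-indexed feature block in the package.
#' `NT_ALPHABET` is the coding-sequence nucleotide alphabet in the A<C<G<T
#' order used for k-mer enumeration and the unit-circle quadrants.
#'
#' @format Character vectors of length 20 and 4.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_ALPHABET
#' @export
NT_ALPHABET <- c("A", "C", "G", "T")

ppi_stop <- function(...) stop(sprintf(...), call. = FALSE)

check_alphabet <- function(seqs, alphabet) {
  allowed <- if (identical(alphabet, "protein")) AA_ALPHABET else NT_ALPHABET
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad)) {
      ppi_stop("record '%s': character '%s' at position %d is not in the %s alphabet",
               names(seqs)[i], chars[bad[1]], bad[1],
               if (identical(alphabet, "protein")) "protein" else "nucleotide")
    }
  }
  invisible(TRUE)
}

#' Read a FASTA file of protein or coding sequences
#'
#' Sequences are upper-cased and validated against the requested alphabet.
#' A character outside the alphabet is a format error naming the record and
#' position; an empty file yields an empty vector with a warning.
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` (20 residues) or `"dna"` (ACGT).
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) ppi_stop("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  hdr <- grepl("^>", lines)
  if (!hdr[1]) ppi_stop("FASTA file does not start with a header line: %s", path)
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1), collapse = "")
  seqs <- toupper(gsub("\\s", "", seqs))
  out <- stats::setNames(as.character(seqs[as.character(seq_along(ids))]), ids)
  out[is.na(out)] <- ""
  empty <- !nzchar(out)
  if (any(empty)) ppi_stop("record '%s' has no sequence lines", ids[which(empty)[1]])
  check_alphabet(out, alphabet)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-out_ascii_pssm` dialect: two header lines, a residue-order
#' line, then one row per sequence position whose first 20 numeric columns
#' are the log-odds scores. Only the log-odds block is kept; the weighted
#' observed percentages and trailing statistics are skipped.
#'
#' @param path PSSM file.
#' @return An L x 20 numeric matrix of class `"pssm"` with `colnames` set to
#'   the residue order found in the file and attribute `protein_id` taken
#'   from the file name.
#' @export
read_ascii_pssm <- function(path) {
  if (!file.exists(path)) ppi_stop("PSSM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  # residue-order line: 40 single-letter fields (two 20-column blocks) or 20
  order_line <- NA_integer_
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) >= 20 && all(nchar(f) == 1) && all(f %in% AA_ALPHABET)) {
      order_line <- i
      column_order <- f[1:20]
      break
    }
  }
  if (is.na(order_line)) ppi_stop("PSSM file %s: residue-order line missing", path)
  rows <- list()
  for (i in seq(order_line + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break
    f <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", f[1])) break   # trailing K/Lambda statistics
    num <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(num) || !(length(num) %in% c(40L, 42L))) {
      ppi_stop("PSSM file %s: malformed score row at position %s (expected 40 numeric score fields)",
               path, f[1])
    }
    rows[[length(rows) + 1L]] <- num[1:20]
  }
  if (!length(rows)) ppi_stop("PSSM file %s: no score rows found", path)
  m <- do.call(rbind, rows)
  colnames(m) <- column_order
  attr(m, "protein_id") <- sub("\\.[^.]*$", "", basename(path))
  class(m) <- c("pssm", class(m))
  m
}

#' Write a score matrix in the PSI-BLAST ASCII PSSM dialect
#'
#' Intended for synthetic fixtures and round-trip testing of
#' [read_ascii_pssm()].
#'
#' @param scores L x 20 numeric matrix; `colnames` give the residue column
#'   order (defaults to the PSI-BLAST order).
#' @param path Output file.
#' @param residues Optional length-L residue vector for the second column.
#' @export
write_ascii_pssm <- function(scores, path, residues = NULL) {
  stopifnot(ncol(scores) == 20L)
  ord <- colnames(scores)
  if (is.null(ord)) {
    ord <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
    colnames(scores) <- ord
  }
  if (is.null(residues)) residues <- rep("A", nrow(scores))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("", con)
  writeLines("Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts", con)
  writeLines(paste0("           ", paste(sprintf("%3s", c(ord, ord)), collapse = "")), con)
  pct <- matrix(0L, nrow(scores), 20L)
  for (i in seq_len(nrow(scores))) {
    writeLines(paste0(sprintf("%5d %s ", i, residues[i]),
                      paste(sprintf("%3d", as.integer(round(scores[i, ]))), collapse = ""),
                      paste(sprintf("%4d", pct[i, ]), collapse = ""),
                      sprintf("  %4.2f %8.2f", 0, 0)), con)
  }
  writeLines("", con)
  writeLines("                      K         Lambda", con)
  writeLines("Standard Ungapped    0.1347     0.3240", con)
  invisible(path)
}

#' Reorder PSSM columns to the fixed residue alphabet
#'
#' @param pssm Matrix from [read_ascii_pssm()] (or any L x 20 matrix with
#'   residue `colnames`).
#' @return The same matrix with columns in [AA_ALPHABET] order.
#' @export
pssm_in_alphabet_order <- function(pssm) {
  stopifnot(!is.null(colnames(pssm)), all(AA_ALPHABET %in% colnames(pssm)))
  out <- pssm[, AA_ALPHABET, drop = FALSE]
  attr(out, "protein_id") <- attr(pssm, "protein_id")
  out
}

pair_label_to_int <- function(tok) {
  out <- rep(NA_integer_, length(tok))
  out[tok %in% c("1", "interacting")] <- 1L
  out[tok %in% c("0", "non-interacting")] <- 0L
  bad <- !(tok %in% c("1", "0", "interacting", "non-interacting", "unknown", "NA"))
  if (any(bad)) ppi_stop("unknown pair label token '%s'", tok[which(bad)[1]])
  out
}

#' Read / write a protein-pair table
#'
#' Tab-separated, three columns `id_a`, `id_b`, `label` with labels `1`
#' (interacting), `0` (non-interacting) or `unknown` (prediction mode,
#' stored as `NA`). A header line is optional on read and written on write;
#' write-then-read is the identity.
#'
#' @param path Pair file.
#' @return Data frame with columns `id_a`, `id_b` (character) and `label`
#'   (integer, `NA` for unknown).
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) ppi_stop("pair file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("id_a", "id_b", "label"))
  if (nrow(df) && identical(tolower(df$id_a[1]), "id_a")) df <- df[-1, , drop = FALSE]
  data.frame(id_a = df$id_a, id_b = df$id_b,
             label = pair_label_to_int(df$label), stringsAsFactors = FALSE)
}

#' @rdname read_pairs
#' @param pairs Data frame with columns `id_a`, `id_b`, `label`.
#' @export
write_pairs <- function(pairs, path) {
  lab <- ifelse(is.na(pairs$label), "unknown", as.character(pairs$label))
  utils::write.table(data.frame(pairs$id_a, pairs$id_b, lab),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a subcellular-localization table
#'
#' Tab-separated: protein id, then semicolon-joined compartment names.
#' Rows with an empty compartment set are rejected.
#'
#' @param path Localization file.
#' @return Named list mapping protein id to a character vector of
#'   compartments.
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) ppi_stop("localization file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("id", "compartments"))
  sets <- strsplit(df$compartments, ";", fixed = TRUE)
  sets <- lapply(sets, function(x) x[nzchar(trimws(x))])
  empty <- !lengths(sets)
  if (any(empty)) ppi_stop("protein '%s' has an empty compartment set", df$id[which(empty)[1]])
  stats::setNames(sets, df$id)
}

#' @rdname read_localizations
#' @param loc Named list of compartment vectors.
#' @export
write_localizations <- function(loc, path) {
  utils::write.table(
    data.frame(names(loc), vapply(loc, paste, character(1), collapse = ";")),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CD-HIT cluster file and return representative ids
#'
#' Optional helper for consuming externally produced redundancy-reduction
#' output: the representative sequence (marked `*`) of each cluster is kept.
#'
#' @param path `.clstr` file.
#' @return Character vector of representative sequence ids.
#' @export
read_clstr_representatives <- function(path) {
  lines <- readLines(path, warn = FALSE)
  reps <- grep("\\*\\s*$", lines, value = TRUE)
  sub(".*>([^.]+)\\.{3}.*", "\\1", reps)
}
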