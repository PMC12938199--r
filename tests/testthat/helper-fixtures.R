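# Small shared fixtures, built once per test session.

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(NT_ALPHABET, n, replace = TRUE), collapse = "")
}

# A hydropathy scale in which alanine carries the minimum of both
# properties (so phi1 = phi2 = 0 after min-max normalization); used for
# the zero-correlation homopolymer case.
zero_at_A_scale <- function() {
  m <- hydropathy_scale(normalize = FALSE)
  m["A", ] <- apply(m, 2, min) - 1
  apply(m, 2, function(x) (x - min(x)) / (max(x) - min(x)))
}

# One small complete protein (sequence + CDS + PSSM) for map tests.
tiny_protein_inputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      seqs <- vapply(1:6, function(i) random_protein(60 + 7 * i, 100 + i),
                     character(1))
      names(seqs) <- sprintf("T%02d", 1:6)
      cfg <- fixture_config(seed = 42L)
      genes <- vapply(seq_along(seqs), function(i)
        back_translate(seqs[[i]], 200 + i), character(1))
      names(genes) <- names(seqs)
      pssms <- lapply(seq_along(seqs), function(i)
        gen_pssm(seqs[[i]], cfg, 300 + i))
      names(pssms) <- names(seqs)
      cache <<- list(proteins = seqs, genes = genes, pssms = pssms)
    }
    cache
  }
})
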