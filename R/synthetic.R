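# Deterministic sub-seed derivation: every stage of a fixture or pipeline
# run draws its own stream from the master seed so that stages can be
# re-run independently without disturbing each other.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) %% 1000003) * 1009 + offset) %% 2147483629L
}

#' Configuration for the synthetic fixture generator
#'
#' The generator emulates every input of the pipeline: protein sequences,
#' back-translated coding sequences, PSSMs, subcellular localizations, and
#' interaction labels carrying a planted signal. The signal is routed
#' through the mean normalized hydrophobicity of each sequence (an APAAC
#' composition quantity): the protein population holds two composition
#' archetypes - a "sticky", hydrophobic-rich class (fraction
#' `sticky_fraction`, residue weights exponentially tilted by `+effect`
#' along the hydrophobicity scale) and a hydrophilic-rich class (tilt
#' `-effect`) - a pair interacts when the sum of the two proteins' mean
#' hydrophobicities exceeds the quantile matching `positive_rate`, and
#' labels are then flipped with probability `noise`. The bimodal tilt
#' gives interacting and non-interacting pairs a real margin, so the
#' planted signal is learnable at desk scale.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Sequence length range (inclusive); the lower bound
#'   keeps fixtures above the length-50 dataset filter.
#' @param composition Base residue weights (length 20, [AA_ALPHABET]
#'   order).
#' @param effect Planted-signal effect size: the magnitude of the
#'   per-class hydrophobicity tilt (0 removes the signal).
#' @param sticky_fraction Fraction of proteins in the hydrophobic-rich
#'   class.
#' @param positive_rate Fraction of all unordered pairs labeled
#'   interacting.
#' @param noise Label flip probability, in `[0, 0.5)`.
#' @param pssm_range Integer score range of the synthetic PSSMs.
#' @param pssm_bias Positive score bias added to each position's own
#'   residue column.
#' @param compartments Compartment names for localization assignment.
#' @param second_compartment_prob Probability that a protein is annotated
#'   to a second compartment.
#' @param seed Master seed; all stages derive sub-seeds from it.
#' @return A list of class `"fixture_config"`.
#' @export
fixture_config <- function(n_proteins = 100L,
                           length_range = c(60L, 400L),
                           composition = rep(1 / 20, 20L),
                           effect = 2,
                           sticky_fraction = 0.3,
                           positive_rate = 0.08,
                           noise = 0,
                           pssm_range = c(-8L, 12L),
                           pssm_bias = 6L,
                           compartments = c("nucleus", "cytoplasm",
                                            "membrane", "mitochondrion"),
                           second_compartment_prob = 0.1,
                           seed = 1L) {
  if (noise < 0 || noise >= 0.5) ppi_stop("noise rate must be in [0, 0.5)")
  if (length_range[1] < 50L) ppi_stop("fixture lengths must be >= 50 to pass the dataset filter")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 composition = composition / sum(composition),
                 effect = effect, sticky_fraction = sticky_fraction,
                 positive_rate = positive_rate,
                 noise = noise, pssm_range = as.integer(pssm_range),
                 pssm_bias = as.integer(pssm_bias),
                 compartments = compartments,
                 second_compartment_prob = second_compartment_prob,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate random protein sequences
#'
#' Residues are drawn i.i.d. from the configured composition,
#' exponentially tilted along the hydrophobicity scale with the
#' protein's class tilt (`+effect` for the sticky class, `-effect`
#' otherwise; see [fixture_config()]).
#'
#' @param config A [fixture_config()].
#' @return Named character vector of protein sequences (`P001`, ...).
#' @export
gen_proteins <- function(config) {
  scale <- hydropathy_scale()
  phi1 <- scale[, "hydrophobicity"]
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_proteins
    lens <- sample(config$length_range[1]:config$length_range[2], n, replace = TRUE)
    sticky <- stats::runif(n) < config$sticky_fraction
    tilts <- ifelse(sticky, config$effect, -config$effect)
    seqs <- vapply(seq_len(n), function(i) {
      w <- config$composition * exp(tilts[i] * phi1)
      paste(sample(AA_ALPHABET, lens[i], replace = TRUE, prob = w / sum(w)),
            collapse = "")
    }, character(1))
    stats::setNames(seqs, sprintf("P%03d", seq_len(n)))
  })
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[setdiff(unique(gc), "*")]
}

#' Back-translate a protein to a coding sequence
#'
#' Each residue is replaced by a codon drawn uniformly from its
#' standard-genetic-code codons, so translating the result recovers the
#' protein and `N = 3 * L`.
#'
#' @param seq Protein sequence.
#' @param seed Integer seed.
#' @return Nucleotide string of length `3 * nchar(seq)`.
#' @export
back_translate <- function(seq, seed) {
  codons <- codon_table()
  chars <- seq_to_chars(seq)
  with_seed(seed, {
    paste(vapply(chars, function(a) {
      cc <- codons[[a]]
      cc[sample.int(length(cc), 1L)]
    }, character(1)), collapse = "")
  })
}

#' Generate a synthetic PSSM for a protein
#'
#' Integer scores drawn uniformly from the configured range, with a
#' positive bias added to each position's own residue column. The result
#' exercises the evolutionary descriptors and the ASCII PSSM round trip;
#' it is synthetic, not biologically calibrated.
#'
#' @param seq Protein sequence.
#' @param config A [fixture_config()].
#' @param seed Integer seed.
#' @return L x 20 integer matrix of class `"pssm"`, columns in PSI-BLAST
#'   order.
#' @export
gen_pssm <- function(seq, config, seed) {
  chars <- seq_to_chars(seq)
  L <- length(chars)
  ord <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  with_seed(seed, {
    m <- matrix(sample(config$pssm_range[1]:config$pssm_range[2], L * 20L,
                       replace = TRUE), L, 20L)
    colnames(m) <- ord
    m[cbind(seq_len(L), match(chars, ord))] <-
      m[cbind(seq_len(L), match(chars, ord))] + config$pssm_bias
    class(m) <- c("pssm", class(m))
    m
  })
}

#' Generate planted-signal interaction labels and localizations
#'
#' Each protein's latent stickiness is the mean normalized hydrophobicity
#' of its sequence. All unordered pairs are scored by the sum of the two
#' stickiness values; pairs above the `1 - positive_rate` quantile are
#' labeled interacting, then labels are flipped with the configured noise
#' rate. Compartments are assigned independently of the labels, so a
#' fraction of non-interacting pairs is cross-compartment and eligible for
#' localization-based negative sampling.
#'
#' @param proteins Named character vector of sequences.
#' @param config A [fixture_config()].
#' @param seed Integer seed (defaults to a stream derived from the config
#'   master seed).
#' @return List with `pairs` (all unordered pairs with integer labels),
#'   `positives` (label-1 subset), `localizations` (named list), and
#'   `stickiness` (named numeric).
#' @export
gen_interactions <- function(proteins, config, seed = derive_seed(config$seed, 3L)) {
  if (length(proteins) < 2L) ppi_stop("need at least 2 proteins")
  scale <- hydropathy_scale()
  stickiness <- vapply(proteins, function(s)
    mean(scale[seq_to_chars(s), "hydrophobicity"]), numeric(1))
  ids <- names(proteins)
  cmb <- utils::combn(length(ids), 2L)
  score <- stickiness[cmb[1, ]] + stickiness[cmb[2, ]]
  thr <- stats::quantile(score, 1 - config$positive_rate, names = FALSE)
  lab <- as.integer(score > thr)
  with_seed(seed, {
    if (config$noise > 0) {
      flip <- stats::runif(length(lab)) < config$noise
      lab[flip] <- 1L - lab[flip]
    }
    loc <- lapply(seq_along(ids), function(i) {
      first <- sample(config$compartments, 1L)
      if (stats::runif(1) < config$second_compartment_prob) {
        unique(c(first, sample(config$compartments, 1L)))
      } else first
    })
  })
  pairs <- data.frame(id_a = ids[cmb[1, ]], id_b = ids[cmb[2, ]],
                      label = lab, stringsAsFactors = FALSE)
  list(pairs = pairs,
       positives = pairs[pairs$label == 1L, , drop = FALSE],
       localizations = stats::setNames(loc, ids),
       stickiness = stickiness)
}

#' Write a complete fixture directory
#'
#' Generates proteins, coding sequences, PSSM files, the positive-pair
#' table and the localization table under `dir`. Fully deterministic under
#' the master seed: two runs produce byte-identical files.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
write_fixtures <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  proteins <- gen_proteins(config)
  genes <- vapply(seq_along(proteins), function(i)
    back_translate(proteins[[i]], derive_seed(config$seed, 100L + i)), character(1))
  names(genes) <- names(proteins)
  pssms <- lapply(seq_along(proteins), function(i)
    gen_pssm(proteins[[i]], config, derive_seed(config$seed, 5000L + i)))
  names(pssms) <- names(proteins)
  net <- gen_interactions(proteins, config)

  write_fasta(proteins, file.path(dir, "proteins.fasta"))
  write_fasta(genes, file.path(dir, "cds.fasta"))
  for (id in names(pssms)) {
    write_ascii_pssm(pssms[[id]], file.path(dir, "pssm", paste0(id, ".pssm")),
                     residues = seq_to_chars(proteins[[id]]))
  }
  write_pairs(net$positives, file.path(dir, "positive_pairs.tsv"))
  write_localizations(net$localizations, file.path(dir, "localizations.tsv"))
  writeLines(c(paste0("seed=", config$seed),
               paste0("n_proteins=", config$n_proteins),
               paste0("positive_rate=", config$positive_rate),
               paste0("effect=", config$effect),
               paste0("noise=", config$noise)),
             file.path(dir, "manifest.txt"))
  invisible(list(proteins = proteins, genes = genes, pssms = pssms,
                 network = net, dir = dir))
}
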