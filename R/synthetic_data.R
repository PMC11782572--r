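# Synthetic genomes with codon-biased exons -------------------------------
#
# Three-base periodicity in real coding sequence comes from codon bias:
# synonymous codons are not used uniformly, so the nucleotide distribution
# differs between the three codon positions. The generator reproduces that
# mechanism directly: exon codons are drawn from a 64-codon categorical with
# probability mass (1 - s) * uniform + s * uniform-over-preferred-codons
# (one fixed preferred codon per amino-acid class), introns are i.i.d.
# nucleotides at a chosen GC content, i.e. a null with no period-3 structure.

BASES <- c("A", "C", "G", "T")

# Standard genetic code: codon -> amino acid (one-letter, "*" = stop).
.codon_table <- function() {
  codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  aa <- vapply(codons, function(cd) {
    b <- strsplit(cd, "")[[1]]
    code <- c(
      TTT = "F", TTC = "F", TTA = "L", TTG = "L",
      CTT = "L", CTC = "L", CTA = "L", CTG = "L",
      ATT = "I", ATC = "I", ATA = "I", ATG = "M",
      GTT = "V", GTC = "V", GTA = "V", GTG = "V",
      TCT = "S", TCC = "S", TCA = "S", TCG = "S",
      CCT = "P", CCC = "P", CCA = "P", CCG = "P",
      ACT = "T", ACC = "T", ACA = "T", ACG = "T",
      GCT = "A", GCC = "A", GCA = "A", GCG = "A",
      TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
      CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
      AAT = "N", AAC = "N", AAA = "K", AAG = "K",
      GAT = "D", GAC = "D", GAA = "E", GAG = "E",
      TGT = "C", TGC = "C", TGA = "*", TGG = "W",
      CGT = "R", CGC = "R", CGA = "R", CGG = "R",
      AGT = "S", AGC = "S", AGA = "R", AGG = "R",
      GGT = "G", GGC = "G", GGA = "G", GGG = "G"
    )
    unname(code[cd])
  }, character(1))
  data.frame(codon = codons, aa = aa, stringsAsFactors = FALSE)
}

# One fixed "preferred" codon per amino-acid class (alphabetically first);
# the point-mass component of the codon distribution sits on this set.
.preferred_codons <- function() {
  tab <- .codon_table()
  tab <- tab[order(tab$aa, tab$codon), ]
  tab$codon[!duplicated(tab$aa)]
}

#' Specification for a synthetic genome
#'
#' Bundles and validates the knobs of the synthetic-genome generator. The
#' defaults are the conditions used throughout the package's tests and
#' examples: strong codon bias (0.9), exons long enough to span at least one
#' 256-sample analysis frame, and introns a few times longer, giving a
#' coding fraction around 30%.
#'
#' @param n_sequences number of sequences to generate.
#' @param exon_length_range two integers, bounds (bp) for exon lengths;
#'   realized lengths are multiples of 3.
#' @param intron_length_range two integers, bounds (bp) for intron lengths.
#' @param exons_per_sequence_range two integers, bounds for the number of
#'   exons per sequence.
#' @param codon_bias_strength real in \[0, 1\]: 0 = uniform codon usage,
#'   1 = all mass on one preferred codon per amino-acid class.
#' @param gc_content real in (0, 1): intron GC content.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return an object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_sequences = 10L,
                                  exon_length_range = c(300L, 600L),
                                  intron_length_range = c(600L, 1500L),
                                  exons_per_sequence_range = c(3L, 5L),
                                  codon_bias_strength = 0.9,
                                  gc_content = 0.5,
                                  seed = 1L) {
  spec <- list(
    n_sequences = check_count(n_sequences, "n_sequences"),
    exon_length_range = check_range(exon_length_range, "exon_length_range", min = 3L),
    intron_length_range = check_range(intron_length_range, "intron_length_range"),
    exons_per_sequence_range = check_range(exons_per_sequence_range,
                                           "exons_per_sequence_range"),
    codon_bias_strength = check_unit(codon_bias_strength, "codon_bias_strength"),
    gc_content = gc_content,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(gc_content) != 1L || !is.finite(gc_content) ||
      gc_content <= 0 || gc_content >= 1) {
    stop_field("gc_content", "must be a single real in (0, 1)")
  }
  class(spec) <- "synthetic_genome_spec"
  spec
}

# 64-codon probability vector for a given bias strength.
codon_probabilities <- function(bias_strength) {
  codons <- .codon_table()$codon
  pref <- .preferred_codons()
  p <- rep((1 - bias_strength) / 64, 64)
  p[codons %in% pref] <- p[codons %in% pref] + bias_strength / length(pref)
  names(p) <- codons
  p
}

.sample_exon <- function(len, probs) {
  stopifnot(len %% 3 == 0)
  paste(sample(names(probs), len %/% 3, replace = TRUE, prob = probs),
        collapse = "")
}

.sample_intron <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
}

# draw an exon length: uniform over multiples of 3 inside the range
.draw_exon_length <- function(range) {
  lo <- ceiling(range[1] / 3)
  hi <- floor(range[2] / 3)
  if (hi < lo) stop_field("exon_length_range", "contains no multiple of 3")
  3L * sample_from(lo:hi, 1L)
}

#' Generate annotated synthetic sequences
#'
#' Each sequence alternates intron and exon segments
#' (intron, exon, ..., exon, intron). Exon segments are concatenations of
#' codons drawn from the biased codon distribution; introns are i.i.d.
#' nucleotides at the configured GC content. Deterministic per spec seed.
#'
#' @param spec a [synthetic_genome_spec()].
#' @return a list of annotated sequences; each element has `id`,
#'   `sequence` (character string over ACGT) and `exons`, an integer matrix
#'   with columns `start`, `end` in 0-based half-open coordinates,
#'   disjoint and sorted.
#' @export
generate_genome <- function(spec) {
  if (!inherits(spec, "synthetic_genome_spec")) {
    stop("'spec' must be created by synthetic_genome_spec()", call. = FALSE)
  }
  probs <- codon_probabilities(spec$codon_bias_strength)
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_sequences), function(i) {
      k <- sample_from(seq(spec$exons_per_sequence_range[1],
                           spec$exons_per_sequence_range[2]), 1L)
      exon_lens <- vapply(seq_len(k), function(.)
        .draw_exon_length(spec$exon_length_range), integer(1))
      intron_lens <- sample_from(seq(spec$intron_length_range[1],
                                     spec$intron_length_range[2]),
                                 k + 1L, replace = TRUE)
      parts <- character(2L * k + 1L)
      exons <- matrix(0L, nrow = k, ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
      pos <- 0L
      for (j in seq_len(k)) {
        parts[2L * j - 1L] <- .sample_intron(intron_lens[j], spec$gc_content)
        pos <- pos + intron_lens[j]
        parts[2L * j] <- .sample_exon(exon_lens[j], probs)
        exons[j, ] <- c(pos, pos + exon_lens[j])
        pos <- pos + exon_lens[j]
      }
      parts[2L * k + 1L] <- .sample_intron(intron_lens[k + 1L], spec$gc_content)
      structure(
        list(id = sprintf("synth_%03d", i),
             sequence = paste(parts, collapse = ""),
             exons = exons),
        class = "annotated_sequence")
    })
  })
}

#' Pure numeric periodic test profile
#'
#' A cosine of the given period plus Gaussian noise; the unit-test signal
#' for anything that claims to detect periodicity.
#'
#' @param length profile length (samples).
#' @param period period in samples, `1 <= period <= length`.
#' @param amplitude cosine amplitude.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed.
#' @return numeric vector of the requested length.
#' @export
generate_periodic_profile <- function(length, period, amplitude = 1,
                                      noise_sd = 0, seed = 1L) {
  length <- check_count(length, "length")
  period <- check_count(period, "period")
  if (period > length) stop_field("period", "must satisfy length >= period")
  with_seed(seed, {
    amplitude * cos(2 * pi * (seq_len(length) - 1) / period) +
      stats::rnorm(length, sd = noise_sd)
  })
}

# FASTA / BED writers ------------------------------------------------------

#' Write sequences as FASTA (wrapped at 70 columns)
#'
#' @param sequences list of annotated sequences (or any list with `id` and
#'   `sequence` fields).
#' @param path output file path.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in sequences) {
    writeLines(paste0(">", s$id), con)
    seq <- s$sequence
    starts <- seq.int(1L, nchar(seq), by = 70L)
    writeLines(substring(seq, starts, pmin(starts + 69L, nchar(seq))), con)
  }
  invisible(path)
}

#' Write exon annotations as 3-column BED
#'
#' 0-based half-open intervals, one row per exon.
#'
#' @inheritParams write_fasta
#' @export
write_bed <- function(sequences, path) {
  rows <- do.call(rbind, lapply(sequences, function(s) {
    if (nrow(s$exons) == 0) return(NULL)
    data.frame(chrom = s$id, start = s$exons[, "start"],
               end = s$exons[, "end"], stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
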