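# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive and separate from the implementation paths it checks.

# naive canonical k-mer histogram by dictionary enumeration
naive_kmer_histogram <- function(seqs, k) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  counts <- new.env(parent = emptyenv())
  for (s in seqs) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    if (length(chars) < k) next
    for (i in seq_len(length(chars) - k + 1L)) {
      w <- chars[i:(i + k - 1L)]
      if (!all(w %in% names(comp))) next
      fwd <- paste(w, collapse = "")
      rev <- paste(rev(unname(comp[w])), collapse = "")
      canon <- if (fwd <= rev) fwd else rev
      counts[[canon]] <- (counts[[canon]] %||% 0L) + 1L
    }
  }
  mult <- unlist(as.list(counts), use.names = FALSE)
  if (is.null(mult)) return(data.frame(multiplicity = integer(0),
                                       count = numeric(0)))
  tab <- table(mult)
  data.frame(multiplicity = as.integer(names(tab)),
             count = as.numeric(tab))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# best local alignment score under blastn scoring (+1/-1, gap open 3,
# gap extend 2; gap of length l costs 3 + 2 l), both strands, via the
# Biostrings dynamic-programming aligner.
oracle_best_local_score <- function(query, ref) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  sc <- function(q) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(ref),
      type = "local", substitutionMatrix = mat,
      gapOpening = 3, gapExtension = 2, scoreOnly = TRUE)
  }
  max(sc(query), sc(revcomp(query)))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant `nsub` substitutions at given (or random) positions
with_substitutions <- function(seq, positions = NULL, nsub = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (is.null(positions)) positions <- sample.int(length(chars), nsub)
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# 60%-repeat genome spec used by the collapse-mechanism tests: a TE-like
# mix of dispersed families plus one satellite-like tandem array.
repeat_rich_spec <- function(total = 1e6, seed = 1) {
  u <- as.integer(0.4 * total)
  s <- total / 1e6
  genome_spec(
    unique_length = u,
    families = list(
      repeat_family("LTR_A", "dispersed", 5000, as.integer(40 * s), 0.01),
      repeat_family("DNA_B", "dispersed", 2000, as.integer(100 * s), 0.01),
      repeat_family("SINE_C", "dispersed", 500, as.integer(200 * s), 0.01),
      repeat_family("SAT_D", "tandem", 50, as.integer(2000 * s), 0.01)),
    seed = seed)
}
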