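#' Construct a k-mer multiplicity histogram object
#'
#' @param counts named numeric vector: names are multiplicities (>= 1),
#'   values are numbers of distinct canonical k-mers at that multiplicity.
#' @param k the word length the histogram was built with (odd), or `NA` when
#'   read from a file that does not record it.
#' @return a `kmer_histogram` data-frame-backed object with columns
#'   `multiplicity` and `count`, ascending multiplicity.
#' @export
kmer_histogram <- function(counts, k) {
  mult <- as.integer(names(counts))
  stopifnot(!anyNA(mult), all(mult >= 1L), all(counts >= 0))
  ord <- order(mult)
  structure(data.frame(multiplicity = mult[ord],
                       count = as.numeric(counts[ord])),
            k = as.integer(k), class = c("kmer_histogram", "data.frame"))
}

#' Count canonical k-mers in a read set
#'
#' Every length-k window over A/C/G/T contributes its canonical form — the
#' lexicographically smaller of the word and its reverse complement — making
#' counts strand-independent. Windows containing any other symbol are
#' skipped. k must be odd (an odd k admits no self-complementary word) and
#' no longer than the reads.
#'
#' @param reads a `read_set`, a named character vector of sequences, or a
#'   path to a FASTA file.
#' @param k odd word length, 1-31 (the classic sweep uses 21-31).
#' @return a [kmer_histogram()]; `sum(multiplicity * count)` equals the
#'   number of valid windows ingested.
#' @export
count_kmers <- function(reads, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) {
    stop("k must be odd (even k admits self-complementary words)")
  }
  seqs <- if (inherits(reads, "read_set")) reads$reads
          else if (is.character(reads) && length(reads) == 1L &&
                   file.exists(reads)) read_fasta(reads)
          else reads
  if (length(seqs) && k > max(nchar(seqs))) {
    stop("k exceeds the read length")
  }
  if (length(seqs) == 0L) {
    return(kmer_histogram(stats::setNames(numeric(0), character(0)), k))
  }
  kmer_histogram(cpp_kmer_histogram(seqs, k), k)
}

#' Modal k-mer coverage
#'
#' The multiplicity with the largest distinct-k-mer count at or above the
#' error cutoff. `"auto"` places the cutoff at the first strict local
#' minimum of counts scanning upward from multiplicity 1 — the valley
#' between the error peak and the genomic peak. Ties break toward the
#' smaller multiplicity.
#'
#' @param hist a [kmer_histogram()].
#' @param error_cutoff minimum multiplicity included, or `"auto"`.
#' @return integer modal multiplicity.
#' @export
modal_kmer_coverage <- function(hist, error_cutoff = "auto") {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (nrow(hist) == 0L) stop("empty k-mer histogram")
  cutoff <- resolve_error_cutoff(hist, error_cutoff)
  h <- hist[hist$multiplicity >= cutoff, ]
  if (nrow(h) == 0L) stop("no multiplicities at or above the error cutoff")
  h$multiplicity[which.max(h$count)]
}

# "auto": first strict local minimum of count scanning upward; error if the
# histogram is monotone decreasing (no genomic peak — coverage too low).
resolve_error_cutoff <- function(hist, error_cutoff) {
  if (!identical(error_cutoff, "auto")) {
    stopifnot(is.numeric(error_cutoff), error_cutoff >= 1)
    return(as.integer(error_cutoff))
  }
  cnt <- hist$count
  if (nrow(hist) == 1L) return(hist$multiplicity[1L])
  for (i in seq_len(nrow(hist) - 1L)) {
    before_ok <- i == 1L || cnt[i] <= cnt[i - 1L]
    if (before_ok && cnt[i + 1L] > cnt[i]) return(hist$multiplicity[i])
  }
  stop("no modal peak: k-mer counts are monotone decreasing ",
       "(coverage too low to separate a genomic peak)")
}

#' Genome size from the k-mer spectrum
#'
#' Total k-mers at or above the error cutoff divided by the modal k-mer
#' coverage. By default multiplicities below the cutoff (sequencing-error
#' k-mers) are excluded from the numerator; set
#' `include_error_kmers = TRUE` for the include-all convention.
#'
#' @inheritParams modal_kmer_coverage
#' @param include_error_kmers include multiplicities below the cutoff in the
#'   total (default FALSE).
#' @return a `kmer_size_estimate` list: `k`, `modal_coverage`,
#'   `error_cutoff`, `genome_size` (bases, rounded).
#' @export
estimate_size_from_kmers <- function(hist, error_cutoff = "auto",
                                     include_error_kmers = FALSE) {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (nrow(hist) == 0L) stop("empty k-mer histogram")
  cutoff <- resolve_error_cutoff(hist, error_cutoff)
  modal <- modal_kmer_coverage(hist, cutoff)
  keep <- if (include_error_kmers) rep(TRUE, nrow(hist))
          else hist$multiplicity >= cutoff
  total <- sum(hist$multiplicity[keep] * hist$count[keep])
  structure(list(k = attr(hist, "k"), modal_coverage = modal,
                 error_cutoff = cutoff,
                 genome_size = round(total / modal)),
            class = "kmer_size_estimate")
}

#' Sweep the k-mer size estimate over word lengths
#'
#' Repeats [count_kmers()] + [estimate_size_from_kmers()] for each k,
#' mirroring the standard 21-31 odd-k sweep.
#'
#' @inheritParams count_kmers
#' @inheritParams estimate_size_from_kmers
#' @param k_values odd word lengths (default `c(21, 23, 25, 27, 29, 31)`).
#' @return data.frame with one row per k: `k`, `modal_coverage`,
#'   `error_cutoff`, `genome_size`.
#' @export
kmer_size_sweep <- function(reads, k_values = seq(21L, 31L, by = 2L),
                            error_cutoff = "auto",
                            include_error_kmers = FALSE) {
  rows <- lapply(k_values, function(k) {
    est <- estimate_size_from_kmers(count_kmers(reads, k),
                                    error_cutoff = error_cutoff,
                                    include_error_kmers = include_error_kmers)
    data.frame(k = k, modal_coverage = est$modal_coverage,
               error_cutoff = est$error_cutoff,
               genome_size = est$genome_size)
  })
  do.call(rbind, rows)
}
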