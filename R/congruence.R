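#' Reverse complement
#' @param x character vector of DNA sequences.
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

# accept a path, a named character vector, or a simulation object
as_contigs <- function(x) {
  if (inherits(x, "simulated_genome") || inherits(x, "collapsed_assembly")) {
    return(x$contigs)
  }
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    return(read_fasta(x))
  }
  stopifnot(is.character(x), !is.null(names(x)))
  x
}

#' Shred an assembly into non-overlapping fixed-length synthetic reads
#'
#' Each contig of length `l` yields `floor(l / fragment_length)` in-order,
#' non-overlapping reads; the trailing remainder shorter than
#' `fragment_length` is dropped and its total recorded.
#'
#' @param assembly FASTA path, named character vector, `simulated_genome` or
#'   `collapsed_assembly`.
#' @param fragment_length read length in bases (default 240).
#' @param label source-assembly label used in reports.
#' @return a `synthetic_read_library`: `reads` (named character),
#'   `fragment_length`, `source`, `provenance` (read_id, contig, start;
#'   1-based) and `dropped_bases`.
#' @export
shred_assembly <- function(assembly, fragment_length = 240L,
                           label = "assembly") {
  stopifnot(fragment_length >= 1L)
  contigs <- as_contigs(assembly)
  fl <- as.integer(fragment_length)
  reads <- character(0)
  prov <- list()
  dropped <- 0L
  for (ctg in names(contigs)) {
    len <- nchar(contigs[[ctg]])
    n <- len %/% fl
    dropped <- dropped + (len - n * fl)
    if (n == 0L) next
    starts <- (seq_len(n) - 1L) * fl + 1L
    frag <- substring(contigs[[ctg]], starts, starts + fl - 1L)
    ids <- sprintf("%s|%s_%d", label, ctg, seq_len(n))
    names(frag) <- ids
    reads <- c(reads, frag)
    prov[[length(prov) + 1L]] <-
      data.frame(read_id = ids, contig = ctg, start = starts)
  }
  structure(list(reads = reads, fragment_length = fl, source = label,
                 provenance = if (length(prov)) do.call(rbind, prov)
                              else NULL,
                 dropped_bases = dropped),
            class = "synthetic_read_library")
}

#' Karlin-Altschul lambda for an ungapped match/mismatch scoring
#'
#' The unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` under the given base
#' composition. For uniform composition with +1/-1 scoring,
#' `lambda = log(3)`.
#'
#' @param base_composition probabilities over A, C, G, T.
#' @param match match reward (> 0).
#' @param mismatch mismatch score (< 0).
#' @return lambda.
#' @export
ka_lambda <- function(base_composition = rep(0.25, 4), match = 1,
                      mismatch = -1) {
  p <- base_composition / sum(base_composition)
  same <- sum(p^2)
  f <- function(lam) same * exp(lam * match) +
    (1 - same) * exp(lam * mismatch) - 1
  uniroot(f, c(1e-9, 20), tol = 1e-12)$root
}

# Karlin-Altschul constant for +1/-1 ungapped scoring; documented value.
KA_K <- 0.333

#' Minimum raw score for an E-value threshold
#'
#' Ungapped Karlin-Altschul: `E = K * m * n * exp(-lambda * S)`; returns the
#' smallest integer score with `E <= evalue`.
#'
#' @param m query length; @param n total reference length.
#' @param evalue E-value threshold.
#' @param lambda from [ka_lambda()]; @param K Karlin-Altschul K.
#' @return integer score threshold.
#' @export
min_score_for_evalue <- function(m, n, evalue = 1e-10,
                                 lambda = log(3), K = KA_K) {
  as.integer(ceiling(log(K * m * n / evalue) / lambda))
}

#' Align a synthetic read library to a reference assembly
#'
#' Seed-and-extend local alignment under blastn-style scoring (reward +1,
#' mismatch -1, gap open 3, gap extend 2; a gap of length l costs
#' `gap_open + gap_extend * l`). Exact seed words of length `word` are
#' hashed over the reference; both strands are searched; up to
#' `max_alignments` highest-scoring alignments per read are reported after
#' dropping any alignment overlapping a better one by more than 50% on the
#' reference. Significance is an ungapped Karlin-Altschul E-value; the
#' default score floor corresponds to `evalue` on this query/reference size.
#'
#' @param library a [shred_assembly()] library (or named character vector of
#'   reads).
#' @param reference FASTA path, named character vector, or simulation object.
#' @param word exact seed word length (default 11, the classic blastn word).
#' @param max_alignments alignments reported per read (default 10).
#' @param evalue E-value threshold used to derive `min_score`.
#' @param min_score raw score floor; overrides `evalue` when given.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return data.frame in BLAST `-outfmt 6` column order (qseqid, sseqid,
#'   pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#'   bitscore) plus a trailing raw `score` column. Minus-strand alignments
#'   have `sstart > send`.
#' @export
align_reads <- function(library, reference, word = 11L,
                        max_alignments = 10L, evalue = 1e-10,
                        min_score = NULL, match = 1L, mismatch = -1L,
                        gap_open = 3L, gap_extend = 2L) {
  reads <- if (inherits(library, "synthetic_read_library")) library$reads
           else library
  refs <- as_contigs(reference)
  if (length(refs) == 0L || all(nchar(refs) == 0L)) {
    stop("empty reference")
  }
  frag_len <- if (inherits(library, "synthetic_read_library")) {
    library$fragment_length
  } else {
    max(nchar(reads))
  }
  if (word > frag_len) stop("seed word length exceeds the fragment length")
  lambda <- ka_lambda(match = match, mismatch = mismatch)
  n_total <- sum(nchar(refs))
  if (is.null(min_score)) {
    min_score <- min_score_for_evalue(frag_len, n_total, evalue,
                                      lambda = lambda)
  }
  res <- cpp_align_reads(unname(reads), names(reads),
                         unname(refs), names(refs),
                         as.integer(word), as.integer(match),
                         as.integer(mismatch), as.integer(gap_open),
                         as.integer(gap_extend), as.integer(min_score),
                         as.integer(max_alignments))
  df <- as.data.frame(res, stringsAsFactors = FALSE)
  df$evalue <- KA_K * frag_len * n_total * exp(-lambda * df$score)
  df$bitscore <- round((lambda * df$score - log(KA_K)) / log(2), 1)
  df[, c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
         "qstart", "qend", "sstart", "send", "evalue", "bitscore", "score")]
}

#' Congruence statistics for one (query assembly, reference assembly) pair
#'
#' Per-read query cover is the fraction of read positions covered by the
#' union of its reported alignment intervals; the mean is over all reads,
#' unmapped reads contributing 0. The high-identity fraction is the
#' proportion of mapped reads whose best-scoring alignment has identity
#' strictly above `identity_threshold`.
#'
#' @param alignments an [align_reads()] table.
#' @param library the [shred_assembly()] library that was aligned.
#' @param identity_threshold percent identity boundary (default 95; strict
#'   inequality).
#' @return a `congruence_result` list: `query`, `reference`,
#'   `mean_query_cover_pct`, `mapped_fraction`, `high_identity_fraction`,
#'   `n_reads`.
#' @export
congruence_stats <- function(alignments, library, reference_label = NA,
                             identity_threshold = 95) {
  stopifnot(inherits(library, "synthetic_read_library"))
  n_reads <- length(library$reads)
  if (n_reads == 0L) stop("empty synthetic read library")
  fl <- library$fragment_length
  cover <- stats::setNames(numeric(n_reads), names(library$reads))
  high <- 0L
  mapped <- 0L
  if (nrow(alignments) > 0L) {
    by_read <- split(alignments, alignments$qseqid)
    for (qid in names(by_read)) {
      al <- by_read[[qid]]
      covered <- logical(fl)
      for (r in seq_len(nrow(al))) {
        covered[al$qstart[r]:al$qend[r]] <- TRUE
      }
      cover[qid] <- sum(covered) / fl
      mapped <- mapped + 1L
      best <- al[order(-al$score, al$sstart), ][1L, ]
      if (best$pident > identity_threshold) high <- high + 1L
    }
  }
  structure(list(query = library$source,
                 reference = reference_label,
                 mean_query_cover_pct = 100 * mean(cover),
                 mapped_fraction = mapped / n_reads,
                 high_identity_fraction = if (mapped > 0L) high / mapped
                                          else NA_real_,
                 n_reads = n_reads),
            class = "congruence_result")
}

#' All-against-all assembly congruence matrix
#'
#' Shreds every assembly into fixed-length synthetic reads, aligns each
#' library to every assembly (self-pairs included), and renders the
#' cross-consistency table: query assemblies in columns, references in
#' rows, each cell `"cover% (high-identity fraction)"`.
#'
#' @param assemblies named list of assemblies (FASTA paths, named character
#'   vectors, or simulation objects).
#' @param fragment_length synthetic read length (default 240).
#' @param ... passed to [align_reads()].
#' @return a `congruence_matrix` list: `results` (data.frame, one row per
#'   ordered pair), `table` (character matrix, formatted cells).
#' @export
congruence_matrix <- function(assemblies, fragment_length = 240L, ...) {
  stopifnot(length(assemblies) >= 2L, !is.null(names(assemblies)))
  labs <- names(assemblies)
  libs <- lapply(labs, function(nm) {
    shred_assembly(assemblies[[nm]], fragment_length, label = nm)
  })
  names(libs) <- labs
  rows <- list()
  tab <- matrix("", length(labs), length(labs),
                dimnames = list(reference = labs, query = labs))
  for (q in labs) {
    for (r in labs) {
      al <- align_reads(libs[[q]], assemblies[[r]], ...)
      st <- congruence_stats(al, libs[[q]], reference_label = r)
      rows[[length(rows) + 1L]] <-
        data.frame(query = q, reference = r,
                   mean_query_cover_pct = st$mean_query_cover_pct,
                   mapped_fraction = st$mapped_fraction,
                   high_identity_fraction = st$high_identity_fraction)
      tab[r, q] <- sprintf("%.2f%% (%.2f)", st$mean_query_cover_pct,
                           st$high_identity_fraction)
    }
  }
  structure(list(results = do.call(rbind, rows), table = tab),
            class = "congruence_matrix")
}
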