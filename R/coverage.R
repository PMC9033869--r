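#' Exact per-base pileup from recorded read placements
#'
#' Computes the depth profile a perfect mapper would produce, using the true
#' origins stored by [simulate_reads()]. No external aligner is involved.
#'
#' @param read_set a `read_set` from [simulate_reads()].
#' @param genome the `simulated_genome` the reads came from (or a named
#'   character vector of contigs, for lengths).
#' @return named list of integer depth vectors, one per contig.
#' @export
depth_from_placements <- function(read_set, genome) {
  contigs <- if (inherits(genome, "simulated_genome")) genome$contigs
             else genome
  L <- read_set$read_length
  lens <- nchar(contigs)
  out <- lapply(names(contigs), function(ctg) {
    ori <- read_set$origins[read_set$origins$contig == ctg, ]
    len <- lens[[ctg]]
    if (nrow(ori) == 0L) return(integer(len))
    inc <- tabulate(ori$start, nbins = len + 1L)
    dec <- tabulate(pmin(ori$start + L, len + 1L), nbins = len + 1L)
    cumsum(inc - dec)[seq_len(len)]
  })
  names(out) <- names(contigs)
  out
}

#' Project a true-genome depth profile onto a collapsed assembly
#'
#' Every true-genome position maps to an assembly position through the
#' assembly's coordinate map: unique segments shift rigidly; every repeat
#' copy folds onto its retained consensus copy. Depth at an assembly
#' position is the sum of true depth over all positions mapping to it — the
#' pileup an exact mapper would produce against the collapsed assembly, so
#' collapsed repeats show the N-fold depth excess that the modal-coverage
#' estimator exploits.
#'
#' @param profile named list of depth vectors on the true genome.
#' @param assembly a `collapsed_assembly` from [collapse_assembly()].
#' @return named list of depth vectors on the assembly contigs.
#' @export
project_depth <- function(profile, assembly) {
  stopifnot(inherits(assembly, "collapsed_assembly"))
  lens <- nchar(assembly$contigs)
  out <- lapply(lens, integer)
  cm <- assembly$coord_map
  for (r in seq_len(nrow(cm))) {
    src <- profile[[cm$src_contig[r]]][cm$src_start[r]:cm$src_end[r]]
    dst <- cm$dst_contig[r]
    idx <- cm$dst_start[r] + seq_along(src) - 1L
    out[[dst]][idx] <- out[[dst]][idx] + src
  }
  out
}

#' Histogram of depth values over all positions
#'
#' @param profile named list (or single vector) of integer depths.
#' @return data.frame with columns `depth` and `sites`, ascending depth;
#'   `sum(sites)` equals the number of positions and
#'   `sum(depth * sites)` the total mapped bases.
#' @export
depth_histogram <- function(profile) {
  if (!is.list(profile)) profile <- list(profile)
  d <- unlist(profile, use.names = FALSE)
  if (length(d) == 0L) stop("empty depth profile")
  stopifnot(all(d >= 0L))
  tab <- table(d)
  data.frame(depth = as.integer(names(tab)),
             sites = as.numeric(tab))
}

#' Modal depth (the coverage peak)
#'
#' The depth with the largest site count at or above `min_depth`. Zero-depth
#' sites are always excluded (uncovered or unmappable sites would otherwise
#' dominate sparse profiles); ties break toward the smaller depth.
#'
#' @param hist a [depth_histogram()] data.frame.
#' @param min_depth smallest depth eligible as the mode (default 1).
#' @param smooth apply a width-3 moving average to site counts before peak
#'   picking (off by default; the raw peak is used).
#' @return integer modal depth.
#' @export
modal_depth <- function(hist, min_depth = 1L, smooth = FALSE) {
  h <- hist[hist$depth >= max(1L, min_depth), ]
  if (nrow(h) == 0L) stop("no sites at or above min_depth")
  sites <- h$sites
  if (smooth && nrow(h) >= 3L) {
    sites <- stats::filter(sites, rep(1 / 3, 3), sides = 2)
    sites[is.na(sites)] <- h$sites[is.na(sites)]
  }
  h$depth[which.max(sites)]
}

#' Genome size from summed depth over modal depth
#'
#' `G = sum(depth) / M`: all per-base depths (zero-depth positions contribute
#' 0 to the sum but are excluded from the modal search) divided by the modal
#' depth M. A repeat collapsed N-fold piles up depth centred on `N * M`, so
#' each of its assembly positions is counted N times and the true size is
#' recovered in the noiseless limit.
#'
#' @inheritParams modal_depth
#' @param profile named list of integer depth vectors.
#' @return a `mapping_size_estimate` list: `modal_depth`,
#'   `total_mapped_bases`, `genome_size` (rounded to nearest integer).
#' @export
estimate_size_from_depth <- function(profile, min_depth = 1L,
                                     smooth = FALSE) {
  hist <- depth_histogram(profile)
  m <- modal_depth(hist, min_depth = min_depth, smooth = smooth)
  total <- sum(hist$depth * hist$sites)
  structure(list(modal_depth = m, total_mapped_bases = total,
                 genome_size = round(total / m)),
            class = "mapping_size_estimate")
}

#' Lander-Waterman genome size
#'
#' `G = N * L / C` for N reads of mean length L at modal coverage C.
#'
#' @param n_reads number of reads N (> 0).
#' @param read_length mean read length L (> 0).
#' @param modal_coverage modal coverage C (> 0).
#' @return genome size in bases.
#' @export
lander_waterman_size <- function(n_reads, read_length, modal_coverage) {
  if (any(c(n_reads, read_length, modal_coverage) <= 0)) {
    stop("n_reads, read_length and modal_coverage must be positive")
  }
  n_reads * read_length / modal_coverage
}
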