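#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; non-ACGT symbols are preserved (downstream k-mer
#' windows and alignment seeds skip them). Duplicate record names and empty
#' files are rejected.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stop("not a FASTA file (no leading '>'): ", path)
  names_full <- sub("^>", "", lines[hdr])
  nm <- sub("\\s.*$", "", names_full)
  if (anyDuplicated(nm)) stop("duplicate sequence names in ", path)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1L))
  out <- character(length(nm))
  names(out) <- nm
  # records with zero body lines stay ""
  out[as.integer(names(seqs))] <- toupper(seqs)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param line_width wrap width in bases (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 60) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n > 0L) {
      starts <- seq(1L, n, by = line_width)
      writeLines(substring(s, starts, pmin(starts + line_width - 1L, n)), con)
    }
  }
  invisible(path)
}

#' Write reads as FASTQ with a constant quality character
#' @param seqs named character vector of reads.
#' @param path output path.
#' @param quality_char single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  stopifnot(nchar(quality_char) == 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(rbind(paste0("@", names(seqs)),
                   seqs,
                   "+",
                   vapply(nchar(seqs),
                          function(n) strrep(quality_char, n),
                          character(1L))),
             con)
  invisible(path)
}

#' Write annotation intervals as BED (0-based, half-open)
#'
#' Internal intervals are 1-based closed; this converts at the boundary.
#'
#' @param annotations data.frame with columns contig, start, end, label.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotations, path) {
  bed <- data.frame(chrom = annotations$contig,
                    chromStart = annotations$start - 1L,
                    chromEnd = annotations$end,
                    name = annotations$label)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a k-mer multiplicity histogram as 2-column TSV
#'
#' The dialect matches `jellyfish histo` output: multiplicity then number of
#' distinct canonical k-mers, tab- or space-separated, no header.
#'
#' @param path file path.
#' @return for the reader, a [kmer_histogram()] object (k is unknown from the
#'   file and recorded as `NA`).
#' @export
read_kmer_histogram <- function(path) {
  tab <- read.table(path, header = FALSE,
                    col.names = c("multiplicity", "count"))
  kmer_histogram(stats::setNames(as.numeric(tab$count),
                                 tab$multiplicity), k = NA_integer_)
}

#' @rdname read_kmer_histogram
#' @param hist a [kmer_histogram()] object.
#' @export
write_kmer_histogram <- function(hist, path) {
  write.table(data.frame(multiplicity = hist$multiplicity,
                         count = hist$count),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-base depth table (samtools-depth layout)
#'
#' Three tab-separated columns: reference name, 1-based position, depth.
#' Positions may be sparse; missing positions are depth 0. Reference lengths
#' default to the largest position seen per reference.
#'
#' @param path TSV path.
#' @param ref_lengths optional named integer vector of reference lengths.
#' @return named list of integer depth vectors (a depth profile).
#' @export
read_depth_tsv <- function(path, ref_lengths = NULL) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("ref", "pos", "depth"),
                    colClasses = c("character", "integer", "integer"))
  refs <- unique(tab$ref)
  out <- lapply(refs, function(r) {
    sub <- tab[tab$ref == r, ]
    len <- if (!is.null(ref_lengths)) ref_lengths[[r]] else max(sub$pos)
    d <- integer(len)
    d[sub$pos] <- sub$depth
    d
  })
  names(out) <- refs
  out
}

#' @rdname read_depth_tsv
#' @param profile named list of integer depth vectors.
#' @param keep_zero write zero-depth positions too (default FALSE, matching
#'   `samtools depth` without `-a`).
#' @export
write_depth_tsv <- function(profile, path, keep_zero = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in names(profile)) {
    d <- profile[[r]]
    pos <- if (keep_zero) seq_along(d) else which(d > 0L)
    if (length(pos)) {
      writeLines(paste(r, pos, d[pos], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with a `seed` and per-module parameter blocks.
#' @return named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
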