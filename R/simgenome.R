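#' Specify a repeat family
#'
#' A repeat family is either `dispersed` (copies scattered at non-overlapping
#' positions, the transposable-element caricature) or `tandem` (copies
#' adjacent in a single array, the satellite caricature). Each copy is an
#' independently mutated instance of the family consensus: every base is
#' substituted with probability `divergence`.
#'
#' @param family_id label used in annotations.
#' @param kind `"dispersed"` or `"tandem"`.
#' @param unit_length repeat unit length in bases (>= 1).
#' @param copy_number number of copies (>= 1).
#' @param divergence per-base substitution probability in `[0, 0.5)` of each
#'   copy relative to the consensus.
#' @return a `repeat_family_spec` object.
#' @export
repeat_family <- function(family_id, kind = c("dispersed", "tandem"),
                          unit_length, copy_number, divergence = 0) {
  kind <- match.arg(kind)
  stopifnot(unit_length >= 1, copy_number >= 1,
            divergence >= 0, divergence < 0.5)
  structure(list(family_id = as.character(family_id), kind = kind,
                 unit_length = as.integer(unit_length),
                 copy_number = as.integer(copy_number),
                 divergence = divergence),
            class = "repeat_family_spec")
}

#' Specify a synthetic genome
#'
#' @param unique_length bases of non-repetitive background sequence (>= 0).
#' @param families list of [repeat_family()] specs.
#' @param sex_pair optional `c(Z = , W = )` lengths for a heteromorphic sex
#'   chromosome pair, added as two extra (unique-sequence) contigs.
#' @param base_composition probabilities over A, C, G, T (sum to 1).
#' @param seed RNG seed; identical spec + seed gives byte-identical output.
#' @return a `genome_spec` object. Its `true_size` is the deterministic sum
#'   `unique_length + sum(unit_length * copy_number) + sum(sex_pair)`.
#' @export
genome_spec <- function(unique_length, families = list(), sex_pair = NULL,
                        base_composition = rep(0.25, 4), seed = NULL) {
  stopifnot(unique_length >= 0,
            all(vapply(families, inherits, logical(1), "repeat_family_spec")))
  if (!is.null(sex_pair)) {
    stopifnot(length(sex_pair) == 2L, all(sex_pair >= 1))
    sex_pair <- as.integer(sex_pair)
    names(sex_pair) <- c("Z", "W")
  }
  repeat_bases <- sum(vapply(families,
                             function(f) f$unit_length * f$copy_number,
                             numeric(1)))
  structure(list(unique_length = as.integer(unique_length),
                 families = families, sex_pair = sex_pair,
                 base_composition = base_composition, seed = seed,
                 true_size = unique_length + repeat_bases +
                   sum(sex_pair %||% 0L)),
            class = "genome_spec")
}

# Random sequential placement of blocks (lengths desc) into a contig of
# length total, without overlap. Returns 1-based start positions in input
# order, or errors after `attempts` rejections per block.
place_blocks <- function(block_lengths, total, attempts = 2000L) {
  ord <- order(block_lengths, decreasing = TRUE)
  starts <- integer(length(block_lengths))
  occupied_start <- integer(0)
  occupied_end <- integer(0)
  for (i in ord) {
    len <- block_lengths[i]
    placed <- FALSE
    for (try in seq_len(attempts)) {
      s <- sample.int(total - len + 1L, 1L)
      e <- s + len - 1L
      if (!any(s <= occupied_end & e >= occupied_start)) {
        occupied_start <- c(occupied_start, s)
        occupied_end <- c(occupied_end, e)
        starts[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place repeat copies without overlap; ",
           "total repeat length too large relative to unique_length")
    }
  }
  starts
}

#' Simulate a genome with controlled repeat structure
#'
#' Builds one main contig: a unique background of `unique_length` bases into
#' which each dispersed repeat copy, and each tandem array as one block, is
#' placed uniformly at random without overlap (rejection sampling; placement
#' feasibility is the caller's responsibility). Optional sex chromosomes are
#' appended as separate contigs. Annotation intervals (1-based, closed)
#' partition every contig; each repeat interval is exactly one unit of its
#' family.
#'
#' @param spec a [genome_spec()].
#' @return a `simulated_genome` with fields `contigs` (named sequences),
#'   `annotations` (data.frame: contig, start, end, label, copy_index),
#'   `families` (consensus sequences per family), `true_size`, and, with a
#'   sex pair, `sex_average` = (Z + W) / 2 — what read-based estimators see
#'   instead of Z + W.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  local_seed(spec$seed)
  comp <- spec$base_composition

  consensus <- lapply(spec$families, function(f) random_dna(f$unit_length, comp))
  names(consensus) <- vapply(spec$families, `[[`, character(1), "family_id")
  if (anyDuplicated(names(consensus))) stop("duplicate family_id")

  # one block per dispersed copy; one block per tandem array
  blk_fam <- integer(0); blk_copy <- integer(0); blk_len <- integer(0)
  for (fi in seq_along(spec$families)) {
    f <- spec$families[[fi]]
    if (f$kind == "dispersed") {
      blk_fam <- c(blk_fam, rep(fi, f$copy_number))
      blk_copy <- c(blk_copy, seq_len(f$copy_number))
      blk_len <- c(blk_len, rep(f$unit_length, f$copy_number))
    } else {
      blk_fam <- c(blk_fam, fi)
      blk_copy <- c(blk_copy, NA_integer_)
      blk_len <- c(blk_len, f$unit_length * f$copy_number)
    }
  }

  main_len <- spec$unique_length + sum(blk_len)
  unique_seq <- random_dna(spec$unique_length, comp)

  ann <- list()
  if (length(blk_len) == 0L) {
    contig <- unique_seq
    if (spec$unique_length > 0L) {
      ann[[1L]] <- data.frame(contig = "chr1", start = 1L,
                              end = spec$unique_length, label = "unique",
                              copy_index = NA_integer_)
    }
  } else {
    starts <- place_blocks(blk_len, main_len)
    ord <- order(starts)
    pieces <- character(0)
    cursor <- 1L      # next genome position to fill
    uq_cursor <- 1L   # next unused unique-background base
    add_unique <- function(upto) {
      # fill [cursor, upto] with unique background
      n <- upto - cursor + 1L
      if (n <= 0L) return(invisible(NULL))
      pieces[[length(pieces) + 1L]] <<-
        substr(unique_seq, uq_cursor, uq_cursor + n - 1L)
      ann[[length(ann) + 1L]] <<-
        data.frame(contig = "chr1", start = cursor, end = upto,
                   label = "unique", copy_index = NA_integer_)
      uq_cursor <<- uq_cursor + n
      cursor <<- upto + 1L
      invisible(NULL)
    }
    for (b in ord) {
      add_unique(starts[b] - 1L)
      f <- spec$families[[blk_fam[b]]]
      if (f$kind == "dispersed") {
        copy_seq <- mutate_sequence(consensus[[blk_fam[b]]], f$divergence)
        pieces[[length(pieces) + 1L]] <- copy_seq
        ann[[length(ann) + 1L]] <-
          data.frame(contig = "chr1", start = cursor,
                     end = cursor + f$unit_length - 1L,
                     label = f$family_id, copy_index = blk_copy[b])
        cursor <- cursor + f$unit_length
      } else {
        for (ci in seq_len(f$copy_number)) {
          unit <- mutate_sequence(consensus[[blk_fam[b]]], f$divergence)
          pieces[[length(pieces) + 1L]] <- unit
          ann[[length(ann) + 1L]] <-
            data.frame(contig = "chr1", start = cursor,
                       end = cursor + f$unit_length - 1L,
                       label = f$family_id, copy_index = ci)
          cursor <- cursor + f$unit_length
        }
      }
    }
    add_unique(main_len)
    contig <- paste(pieces, collapse = "")
  }

  contigs <- c(chr1 = contig)
  if (!is.null(spec$sex_pair)) {
    zseq <- random_dna(spec$sex_pair[["Z"]], comp)
    wseq <- random_dna(spec$sex_pair[["W"]], comp)
    contigs <- c(contigs, Z = zseq, W = wseq)
    ann[[length(ann) + 1L]] <-
      data.frame(contig = "Z", start = 1L, end = spec$sex_pair[["Z"]],
                 label = "unique", copy_index = NA_integer_)
    ann[[length(ann) + 1L]] <-
      data.frame(contig = "W", start = 1L, end = spec$sex_pair[["W"]],
                 label = "unique", copy_index = NA_integer_)
  }
  annotations <- do.call(rbind, ann)

  g <- structure(list(contigs = contigs, annotations = annotations,
                      families = spec$families, consensus = consensus,
                      true_size = sum(nchar(contigs))),
                 class = "simulated_genome")
  if (!is.null(spec$sex_pair)) {
    g$sex_average <- mean(spec$sex_pair)
  }
  stopifnot(g$true_size == spec$true_size)
  g
}

#' Duplicate a genome into a diploid pair of haplotypes
#'
#' The second haplotype carries heterozygous substitutions at rate
#' `het_rate`. Intended for studying how heterozygosity perturbs the k-mer
#' spectrum; estimators treat modal coverage as diploid coverage.
#'
#' @param genome a `simulated_genome`.
#' @param het_rate per-base heterozygous substitution probability.
#' @param seed RNG seed.
#' @return a `simulated_genome` with each contig duplicated (`*_hap2`);
#'   `true_size` doubles (2C content).
#' @export
diploid_copy <- function(genome, het_rate = 0.001, seed = NULL) {
  stopifnot(inherits(genome, "simulated_genome"))
  local_seed(seed)
  hap2 <- vapply(genome$contigs, mutate_sequence, character(1),
                 rate = het_rate)
  names(hap2) <- paste0(names(genome$contigs), "_hap2")
  ann2 <- genome$annotations
  ann2$contig <- paste0(ann2$contig, "_hap2")
  genome$contigs <- c(genome$contigs, hap2)
  genome$annotations <- rbind(genome$annotations, ann2)
  genome$true_size <- sum(nchar(genome$contigs))
  genome
}

# vectorized i.i.d. substitution errors over a read vector (constant length L)
apply_read_errors <- function(reads, read_length, error_rate) {
  if (error_rate <= 0) return(reads)
  n_err <- rbinom(length(reads), read_length, error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(read_length, n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate uniformly placed reads with substitution errors
#'
#' Read count is `N = ceiling(target_coverage * true_size / read_length)`.
#' Reads are distributed over contigs proportionally to the number of valid
#' start positions (`length - L + 1`), with uniform starts within a contig.
#' True placements are recorded for oracle use (exact pileups without a
#' mapper).
#'
#' @param genome a `simulated_genome` (or any named character vector of
#'   contigs).
#' @param target_coverage fold coverage C (> 0).
#' @param read_length read length L in bases; must not exceed the shortest
#'   contig.
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @return a `read_set`: `reads` (named character), `read_length`, `count`,
#'   `error_rate`, and `origins` (data.frame read_id, contig, start; 1-based).
#' @export
simulate_reads <- function(genome, target_coverage, read_length,
                           error_rate = 0, seed = NULL) {
  contigs <- if (inherits(genome, "simulated_genome")) genome$contigs
             else genome
  if (target_coverage <= 0 || read_length <= 0) {
    stop("target_coverage and read_length must be positive")
  }
  lens <- nchar(contigs)
  if (read_length > min(lens)) {
    stop("read_length exceeds the shortest contig")
  }
  local_seed(seed)
  g <- sum(lens)
  n <- as.integer(ceiling(target_coverage * g / read_length))
  valid <- lens - read_length + 1L
  ctg_idx <- sample.int(length(contigs), n, replace = TRUE,
                        prob = valid / sum(valid))
  starts <- 1L + as.integer(floor(runif(n) * valid[ctg_idx]))
  reads <- substring(contigs[ctg_idx], starts, starts + read_length - 1L)
  reads <- apply_read_errors(reads, read_length, error_rate)
  ids <- sprintf("read%06d", seq_len(n))
  names(reads) <- ids
  structure(list(reads = reads, read_length = as.integer(read_length),
                 count = n, error_rate = error_rate,
                 origins = data.frame(read_id = ids,
                                      contig = names(contigs)[ctg_idx],
                                      start = starts)),
            class = "read_set")
}

#' Collapse the repeat families of a simulated genome into an "assembly"
#'
#' Emulates the assembler failure mode in which near-identical repeat copies
#' are merged: each dispersed family is represented by
#' `retained_copies_per_family` consensus copies, each tandem array is
#' truncated to that many consensus units, and unique sequence is untouched.
#' With no repeat families the operation is the identity on total length.
#'
#' @param genome a `simulated_genome`.
#' @param retained_copies_per_family copies kept per family (>= 1).
#' @return a `collapsed_assembly`: `contigs`, `length`, `collapse_map`
#'   (true copies represented by each retained copy, per family), and
#'   `coord_map`, a data.frame mapping every true-genome interval to its
#'   assembly interval (used for exact projected pileups).
#' @export
collapse_assembly <- function(genome, retained_copies_per_family = 1L) {
  stopifnot(inherits(genome, "simulated_genome"),
            retained_copies_per_family >= 1L)
  retain <- as.integer(retained_copies_per_family)
  fam_ids <- vapply(genome$families, `[[`, character(1), "family_id")
  copy_counts <- stats::setNames(
    vapply(genome$families, `[[`, integer(1), "copy_number"), fam_ids)

  out_contigs <- character(0)
  map <- list()
  # assembly position of each retained slot: slot_pos[[family]][slot]
  slot_pos <- lapply(copy_counts, function(cc) rep(NA_integer_, min(retain, cc)))

  for (ctg in names(genome$contigs)) {
    ann <- genome$annotations[genome$annotations$contig == ctg, ]
    ann <- ann[order(ann$start), ]
    pieces <- character(0)
    cursor <- 1L
    pending <- list()  # src intervals awaiting slot positions
    for (r in seq_len(nrow(ann))) {
      a <- ann[r, ]
      len <- a$end - a$start + 1L
      if (a$label == "unique") {
        pieces[[length(pieces) + 1L]] <-
          substr(genome$contigs[[ctg]], a$start, a$end)
        map[[length(map) + 1L]] <-
          data.frame(src_contig = ctg, src_start = a$start, src_end = a$end,
                     dst_contig = ctg, dst_start = cursor)
        cursor <- cursor + len
      } else {
        fam <- a$label
        n_slots <- length(slot_pos[[fam]])
        slot <- ((a$copy_index - 1L) %% n_slots) + 1L
        if (a$copy_index <= n_slots) {
          # retained: emit the consensus at this position
          pieces[[length(pieces) + 1L]] <- genome$consensus[[fam]]
          slot_pos[[fam]][slot] <- cursor
          attr(slot_pos[[fam]], "contig") <- ctg
          cursor <- cursor + len
        }
        pending[[length(pending) + 1L]] <-
          list(fam = fam, slot = slot, src_contig = ctg,
               src_start = a$start, src_end = a$end)
      }
    }
    out_contigs[[ctg]] <- paste(pieces, collapse = "")
    for (p in pending) {
      map[[length(map) + 1L]] <-
        data.frame(src_contig = p$src_contig, src_start = p$src_start,
                   src_end = p$src_end,
                   dst_contig = attr(slot_pos[[p$fam]], "contig"),
                   dst_start = slot_pos[[p$fam]][p$slot])
    }
  }

  collapse_map <- lapply(copy_counts, function(cc) {
    n_slots <- min(retain, cc)
    vapply(seq_len(n_slots),
           function(s) sum(((seq_len(cc) - 1L) %% n_slots) + 1L == s),
           integer(1))
  })
  structure(list(contigs = out_contigs,
                 length = sum(nchar(out_contigs)),
                 retained_copies_per_family = retain,
                 collapse_map = collapse_map,
                 coord_map = if (length(map)) do.call(rbind, map) else NULL),
            class = "collapsed_assembly")
}
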