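#' Missing DNA: cytometric size minus assembly size
#'
#' @param cytometric_1C_mbp cytometric haploid genome size (Mbp, > 0).
#' @param assembly_mbp assembly size (Mbp, > 0).
#' @return list: `missing_dna_mbp` (may be negative) and `flagged` (TRUE
#'   when the assembly exceeds the cytometric size).
#' @export
missing_dna <- function(cytometric_1C_mbp, assembly_mbp) {
  stopifnot(cytometric_1C_mbp > 0, assembly_mbp > 0)
  d <- cytometric_1C_mbp - assembly_mbp
  if (d < 0) {
    warning("assembly is larger than the cytometric genome size")
  }
  list(missing_dna_mbp = d, flagged = d < 0)
}

#' Partition the cytometric genome into non-repetitive and repetitive DNA
#'
#' The assembly's non-repetitive share, `assembly * (1 - repeat_fraction)`,
#' is assumed fully captured; everything else in the cytometric genome is
#' repetitive and/or uncaptured DNA. Headline figures are rounded to the
#' nearest 100 Mbp (the conventional presentation); exact values are
#' returned alongside.
#'
#' @inheritParams missing_dna
#' @param repeat_fraction fraction of the assembly annotated as repeats, in
#'   `[0, 1]`.
#' @return list with exact values (`non_repetitive_mbp`,
#'   `repetitive_or_uncaptured_mbp`, `repetitive_pct`) and headline values
#'   rounded to 100 Mbp (`headline_*`).
#' @export
repeat_partition <- function(cytometric_1C_mbp, assembly_mbp,
                             repeat_fraction) {
  stopifnot(repeat_fraction >= 0, repeat_fraction <= 1)
  non_rep <- assembly_mbp * (1 - repeat_fraction)
  if (non_rep > cytometric_1C_mbp) {
    stop("non-repetitive assembly content exceeds the cytometric size")
  }
  rep_exact <- cytometric_1C_mbp - non_rep
  hl_non <- round_half_up(non_rep / 100) * 100
  hl_rep <- cytometric_1C_mbp - hl_non
  list(non_repetitive_mbp = non_rep,
       repetitive_or_uncaptured_mbp = rep_exact,
       repetitive_pct = 100 * rep_exact / cytometric_1C_mbp,
       headline_non_repetitive_mbp = hl_non,
       headline_repetitive_mbp = hl_rep,
       headline_repetitive_pct = round_half_up(
         100 * hl_rep / cytometric_1C_mbp))
}

#' Consolidated multi-method genome size report
#'
#' One row per estimation method with its size and the ratio to the
#' reference size — the cytometric measurement for real data, the simulator
#' ground truth for simulations. On a repeat-rich simulated genome the
#' expected ordering is: assembly size < k-mer estimate <= depth estimate
#' ~ true size.
#'
#' @param estimates named numeric vector or list of sizes in Mbp (e.g.
#'   `c(assembly = , kmer = , mapping = , cytometric_1C = )`); at least one.
#' @param reference_mbp reference size (cytometric 1C or simulation truth).
#' @param reference_label label for the reference column.
#' @return data.frame: `method`, `size_mbp`, `ratio_to_<reference_label>`.
#' @export
consolidated_report <- function(estimates, reference_mbp,
                                reference_label = "reference") {
  est <- unlist(estimates)
  stopifnot(length(est) >= 1L, !is.null(names(est)), reference_mbp > 0)
  out <- data.frame(method = names(est), size_mbp = unname(est),
                    ratio = unname(est) / reference_mbp)
  names(out)[3L] <- paste0("ratio_to_", reference_label)
  out
}

#' @export
print.congruence_matrix <- function(x, ...) {
  cat("Assembly congruence (query in columns, reference in rows;",
      "cell = mean query cover % (fraction of mapped reads > 95% identity))\n")
  print(x$table, quote = FALSE)
  invisible(x)
}

#' @export
print.congruence_result <- function(x, ...) {
  cat(sprintf(
    "congruence %s -> %s: mean query cover %.2f%%, mapped %.3f, >95%% id %.3f (n=%d)\n",
    x$query, x$reference, x$mean_query_cover_pct, x$mapped_fraction,
    x$high_identity_fraction, x$n_reads))
  invisible(x)
}

#' @export
print.cytometry_record <- function(x, ...) {
  cat(sprintf("%s [%s]: 2C %.3f pg (%.2f Gb), 1C %.3f pg (%.2f Gb)\n",
              x$specimen, x$method, x$two_C_pg, x$two_C_gb, x$one_C_pg,
              x$one_C_gb))
  invisible(x)
}

#' @export
print.simulated_genome <- function(x, ...) {
  rep_bases <- with(x$annotations,
                    sum((end - start + 1)[label != "unique"]))
  cat(sprintf("simulated genome: %d contig(s), true size %d bp, %.1f%% repeat\n",
              length(x$contigs), x$true_size, 100 * rep_bases / x$true_size))
  invisible(x)
}

#' @export
print.collapsed_assembly <- function(x, ...) {
  cat(sprintf("collapsed assembly: %d contig(s), %d bp (retained %d cop%s per family)\n",
              length(x$contigs), x$length, x$retained_copies_per_family,
              if (x$retained_copies_per_family == 1L) "y" else "ies"))
  invisible(x)
}
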