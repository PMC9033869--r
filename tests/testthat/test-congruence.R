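test_that("shredding tiles contigs and drops the remainder", {
  asm <- c(ctg = random_seq(1000))
  lib <- shred_assembly(asm, 240)
  expect_equal(length(lib$reads), 4L)
  expect_equal(lib$dropped_bases, 40L)
  expect_true(all(nchar(lib$reads) == 240L))
  expect_equal(unname(lib$reads[1L]), substr(asm[["ctg"]], 1, 240))

  expect_equal(length(shred_assembly(c(a = random_seq(240)), 240)$reads), 1L)
  expect_equal(length(shred_assembly(c(a = random_seq(239)), 240)$reads), 0L)
})

test_that("lambda solves the Karlin-Altschul equation", {
  expect_equal(ka_lambda(), log(3), tolerance = 1e-9)
  # skewed composition: check the defining identity directly
  p <- c(0.4, 0.1, 0.1, 0.4)
  lam <- ka_lambda(p)
  same <- sum(p^2)
  expect_equal(same * exp(lam) + (1 - same) * exp(-lam), 1, tolerance = 1e-9)
})

test_that("exact substrings align full-length at 100% identity", {
  set.seed(401)
  ref <- c(chr = random_seq(5000))
  lib <- shred_assembly(ref, 240, label = "self")
  al <- align_reads(lib, ref)
  st <- congruence_stats(al, lib, "self")
  expect_equal(st$mean_query_cover_pct, 100)
  expect_equal(st$mapped_fraction, 1)
  expect_equal(st$high_identity_fraction, 1)
  best <- al[al$qseqid == al$qseqid[1L], ][1L, ]
  expect_equal(best$score, 240L)
  expect_equal(best$pident, 100)
  expect_equal(best$qstart, 1L)
  expect_equal(best$qend, 240L)
})

test_that("12 scattered substitutions sit exactly on the 95% boundary", {
  set.seed(402)
  ref_seq <- random_seq(2000)
  read <- substr(ref_seq, 501, 740)
  read <- with_substitutions(read, positions = seq(10, 230, by = 20))
  al <- align_reads(stats::setNames(read, "q"), c(chr = ref_seq),
                    min_score = 30)
  best <- al[order(-al$score), ][1L, ]
  expect_equal(best$score, 228L - 12L)
  expect_lte(best$pident, 95)          # 228/240 = 95%: excluded by strict >
  st <- congruence_stats(al, structure(list(
    reads = c(q = read), fragment_length = 240L, source = "q",
    provenance = NULL, dropped_bases = 0L),
    class = "synthetic_read_library"), "chr")
  expect_equal(st$high_identity_fraction, 0)
})

test_that("random reads stay below the E-value score floor", {
  set.seed(403)
  ref <- c(chr = random_seq(50000))
  foreign <- stats::setNames(vapply(1:40, function(i) random_seq(240),
                                    character(1)),
                             paste0("q", 1:40))
  al <- align_reads(foreign, ref)
  expect_equal(nrow(al), 0L)
})

test_that("reverse-complement reads are found and reported in query coords", {
  set.seed(404)
  ref_seq <- random_seq(3000)
  read <- revcomp(substr(ref_seq, 1001, 1240))
  al <- align_reads(stats::setNames(read, "q"), c(chr = ref_seq))
  expect_equal(nrow(al), 1L)
  expect_equal(al$pident, 100)
  expect_equal(c(al$qstart, al$qend), c(1L, 240L))
  expect_gt(al$sstart, al$send)        # minus strand: descending ref coords
  expect_equal(sort(c(al$sstart, al$send)), c(1001L, 1240L))
})

test_that("best scores equal the full dynamic-programming oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(405)
  for (i in 1:12) {
    ref_seq <- random_seq(1000)
    qlen <- sample(150:400, 1)
    s0 <- sample(1000 - qlen, 1)
    q <- substr(ref_seq, s0, s0 + qlen - 1L)
    q <- with_substitutions(q, nsub = sample(0:10, 1))
    if (i %% 3 == 0) q <- revcomp(q)
    al <- align_reads(stats::setNames(q, "q"), c(chr = ref_seq),
                      min_score = 25)
    expect_gt(nrow(al), 0)
    expect_equal(max(al$score), oracle_best_local_score(q, ref_seq))
  }
})

test_that("gapped alignments score under the stated affine penalties", {
  skip_if_not_installed("Biostrings")
  set.seed(406)
  ref_seq <- random_seq(1200)
  # delete 4 bases from the middle of a 300 bp window: 296 matches, one
  # gap of length 4 on the reference side costing 3 + 2*4
  q <- paste0(substr(ref_seq, 301, 450), substr(ref_seq, 455, 604))
  al <- align_reads(stats::setNames(q, "q"), c(chr = ref_seq),
                    min_score = 25)
  expect_equal(max(al$score), 300 - (3 + 2 * 4))
  expect_equal(max(al$score), oracle_best_local_score(q, ref_seq))
  best <- al[which.max(al$score), ]
  expect_equal(best$gapopen, 1L)
  expect_equal(best$length, 304L)
})

test_that("alignment output is deterministic", {
  set.seed(407)
  asm <- c(chr = random_seq(2000))
  lib <- shred_assembly(asm, 240, label = "a")
  a1 <- align_reads(lib, asm)
  a2 <- align_reads(lib, asm)
  expect_identical(a1, a2)
})

test_that("congruence stats handle empty alignment sets", {
  lib <- structure(list(reads = c(q1 = random_seq(240)),
                        fragment_length = 240L, source = "x",
                        provenance = NULL, dropped_bases = 0L),
                   class = "synthetic_read_library")
  empty <- align_reads(lib, c(chr = random_seq(300)), min_score = 1e6)
  st <- congruence_stats(empty, lib, "chr")
  expect_equal(st$mean_query_cover_pct, 0)
  expect_equal(st$mapped_fraction, 0)
  expect_true(is.na(st$high_identity_fraction))
})

test_that("a pair sharing half its sequence shows ~50% mean query cover", {
  set.seed(408)
  shared <- random_seq(12000)
  a <- c(chr = paste0(shared, random_seq(12000)))
  b <- c(chr = paste0(shared, random_seq(12000)))
  lib <- shred_assembly(a, 240, label = "a")
  st <- congruence_stats(align_reads(lib, b), lib, "b")
  n <- length(lib$reads)
  tol <- 300 * sqrt(0.25 / n)  # binomial on the read count, 3 sigma
  expect_lt(abs(st$mean_query_cover_pct - 50), tol)
})

test_that("divergence between assemblies never raises the >95% fraction", {
  set.seed(409)
  base <- random_seq(8000)
  lib <- shred_assembly(c(chr = base), 240, label = "q")
  fracs <- vapply(c(0, 0.02, 0.06), function(d) {
    ref <- if (d == 0) base else with_substitutions(base, nsub = round(d * 8000))
    congruence_stats(align_reads(lib, c(chr = ref)), lib,
                     "r")$high_identity_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
  expect_equal(fracs[1L], 1)
})

test_that("the congruence matrix covers all ordered pairs", {
  set.seed(410)
  shared <- random_seq(6000)
  asm <- list(A = c(chr = shared),
              B = c(chr = shared),
              C = c(chr = paste0(shared, random_seq(6000))))
  m <- congruence_matrix(asm, fragment_length = 240)
  expect_equal(nrow(m$results), 9L)
  expect_equal(dim(m$table), c(3L, 3L))
  self_aa <- m$results[m$results$query == "A" & m$results$reference == "A", ]
  expect_equal(self_aa$mean_query_cover_pct, 100)
  expect_equal(self_aa$high_identity_fraction, 1)
  # identical assemblies are interchangeable
  ab <- m$results[m$results$query == "A" & m$results$reference == "B", ]
  expect_equal(ab$mean_query_cover_pct, 100)
  # subset-as-query covers fully; superset-as-query does not
  ca <- m$results[m$results$query == "C" & m$results$reference == "A", ]
  ac <- m$results[m$results$query == "A" & m$results$reference == "C", ]
  expect_equal(ac$mean_query_cover_pct, 100)
  expect_lt(ca$mean_query_cover_pct, 100)
})
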