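test_that("genome size is the deterministic sum of the spec", {
  g0 <- simulate_genome(genome_spec(100000, seed = 1))
  expect_equal(g0$true_size, 100000)
  expect_equal(nrow(g0$annotations), 1L)
  expect_equal(g0$annotations$label, "unique")

  spec <- genome_spec(90000,
                      list(repeat_family("fam", "dispersed", 1000, 10, 0)),
                      seed = 2)
  g <- simulate_genome(spec)
  expect_equal(g$true_size, 100000)
  rep_ann <- g$annotations[g$annotations$label == "fam", ]
  expect_equal(nrow(rep_ann), 10L)
  expect_true(all(rep_ann$end - rep_ann$start + 1L == 1000L))
  # zero divergence: all copies identical to the consensus
  copies <- substring(g$contigs[["chr1"]], rep_ann$start, rep_ann$end)
  expect_true(all(copies == g$consensus[["fam"]]))
})

test_that("annotations partition each contig exactly", {
  spec <- repeat_rich_spec(total = 1e5, seed = 3)
  g <- simulate_genome(spec)
  for (ctg in names(g$contigs)) {
    ann <- g$annotations[g$annotations$contig == ctg, ]
    ann <- ann[order(ann$start), ]
    expect_equal(ann$start[1L], 1L)
    expect_equal(ann$end[nrow(ann)], nchar(g$contigs[[ctg]]))
    if (nrow(ann) > 1L) {
      expect_true(all(ann$start[-1L] == ann$end[-nrow(ann)] + 1L))
    }
  }
  # stated repeat fraction is exact by construction
  rep_bases <- with(g$annotations, sum((end - start + 1)[label != "unique"]))
  expect_equal(rep_bases / g$true_size, 0.6, tolerance = 1e-9)
})

test_that("copy divergence matches the binomial model in expectation", {
  spec <- genome_spec(50000,
                      list(repeat_family("fam", "dispersed", 2000, 20, 0.05)),
                      seed = 11)
  g <- simulate_genome(spec)
  ann <- g$annotations[g$annotations$label == "fam", ]
  copies <- substring(g$contigs[["chr1"]], ann$start, ann$end)
  mm <- vapply(copies, function(cp) {
    sum(strsplit(cp, "")[[1L]] != strsplit(g$consensus[["fam"]], "")[[1L]])
  }, numeric(1))
  # 20 copies x Binomial(2000, 0.05): mean 100, sd ~9.7 per copy
  expect_gt(mean(mm), 100 - 3 * 9.75 / sqrt(20))
  expect_lt(mean(mm), 100 + 3 * 9.75 / sqrt(20))
})

test_that("infeasible dispersed placement is rejected", {
  spec <- genome_spec(1000,
                      list(repeat_family("fam", "dispersed", 900, 10, 0)),
                      seed = 4)
  expect_error(simulate_genome(spec), "without overlap")
})

test_that("simulation is byte-identical given spec and seed", {
  spec <- repeat_rich_spec(total = 5e4, seed = 99)
  g1 <- simulate_genome(spec)
  g2 <- simulate_genome(spec)
  expect_identical(g1$contigs, g2$contigs)
  expect_identical(g1$annotations, g2$annotations)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(g1$contigs, f1); write_fasta(g2$contigs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("sex pair contributes contigs and exposes the haploid average", {
  spec <- genome_spec(50000, sex_pair = c(30000, 20000), seed = 5)
  g <- simulate_genome(spec)
  expect_equal(g$true_size, 100000)
  expect_setequal(names(g$contigs), c("chr1", "Z", "W"))
  expect_equal(g$sex_average, 25000)
})

test_that("read simulation honours N = ceiling(C G / L) and origins", {
  g <- simulate_genome(genome_spec(100000, seed = 6))
  rs <- simulate_reads(g, 10, 100, error_rate = 0, seed = 7)
  expect_equal(rs$count, 10000L)
  expect_true(all(nchar(rs$reads) == 100L))
  # error-free reads are exact substrings at their recorded origin
  idx <- sample.int(rs$count, 200)
  expect_true(all(rs$reads[idx] ==
    substring(g$contigs[rs$origins$contig[idx]], rs$origins$start[idx],
              rs$origins$start[idx] + 99L)))
  expect_error(simulate_reads(g, -1, 100), "positive")
  expect_error(simulate_reads(g, 10, 2e5), "shortest contig")
})

test_that("mean interior depth tracks target coverage within 3%", {
  g <- simulate_genome(genome_spec(100000, seed = 8))
  rs <- simulate_reads(g, 30, 240, error_rate = 0, seed = 9)
  depth <- depth_from_placements(rs, g)[["chr1"]]
  interior <- depth[240:(length(depth) - 240L)]
  expect_equal(mean(interior), 30, tolerance = 0.03)
})

test_that("substitution errors occur at the stated rate", {
  g <- simulate_genome(genome_spec(20000, seed = 10))
  rs <- simulate_reads(g, 5, 100, error_rate = 0.02, seed = 11)
  truth <- substring(g$contigs[rs$origins$contig], rs$origins$start,
                     rs$origins$start + 99L)
  mm <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  }, rs$reads, truth)
  expect_equal(mean(mm) / 100, 0.02, tolerance = 0.15)
})

test_that("collapse keeps unique sequence and retains consensus copies", {
  # identity without repeats
  g0 <- simulate_genome(genome_spec(50000, seed = 12))
  expect_equal(collapse_assembly(g0)$length, 50000)

  spec <- genome_spec(90000,
                      list(repeat_family("fam", "dispersed", 1000, 10, 0)),
                      seed = 13)
  asm <- collapse_assembly(simulate_genome(spec), 1L)
  expect_equal(asm$length, 91000)
  expect_equal(asm$collapse_map$fam, 10L)

  tand <- genome_spec(0, list(repeat_family("sat", "tandem", 50, 100, 0)),
                      seed = 14)
  asm2 <- collapse_assembly(simulate_genome(tand), 2L)
  expect_equal(asm2$length, 100)
  expect_equal(asm2$collapse_map$sat, c(50L, 50L))
})

test_that("assembly length is non-increasing in copy number", {
  lens <- vapply(c(5L, 10L, 20L), function(cn) {
    spec <- genome_spec(50000,
                        list(repeat_family("fam", "dispersed", 500, cn, 0)),
                        seed = 15)
    collapse_assembly(simulate_genome(spec))$length
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("coordinate map covers the true genome and targets the assembly", {
  spec <- repeat_rich_spec(total = 1e5, seed = 16)
  g <- simulate_genome(spec)
  asm <- collapse_assembly(g)
  cm <- asm$coord_map
  expect_equal(sum(cm$src_end - cm$src_start + 1L), g$true_size)
  dst_end <- cm$dst_start + (cm$src_end - cm$src_start)
  expect_true(all(dst_end <= nchar(asm$contigs[cm$dst_contig])))
})

test_that("diploid copy doubles size and perturbs the second haplotype", {
  g <- simulate_genome(genome_spec(20000, seed = 17))
  d <- diploid_copy(g, het_rate = 0.01, seed = 18)
  expect_equal(d$true_size, 40000)
  expect_false(d$contigs[["chr1"]] == d$contigs[["chr1_hap2"]])
})
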