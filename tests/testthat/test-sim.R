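test_that("genome construction hits the requested composition and is deterministic", {
  g <- make_genome(c(chrA = 100000L), gc = 0.41, seed = 1)
  s <- g$sequences$chrA
  expect_equal(nchar(s), 100000L)
  gc_obs <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc_obs - 0.41), 0.015)

  g2 <- make_genome(c(chrA = 100000L), gc = 0.41, seed = 1)
  expect_identical(g$sequences, g2$sequences)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted motifs are present verbatim at recorded coordinates", {
  g <- make_genome(c(chrA = 50000L), gc = 0.41,
                   motifs = list(motif = "CCTCAGC", n = 10L), seed = 2)
  expect_equal(nrow(g$motifs), 10L)
  for (i in seq_len(10)) {
    expect_identical(substr(g$sequences$chrA, g$motifs$start[i] + 1L,
                            g$motifs$end[i]), "CCTCAGC")
  }
  ## scanning finds them all (plus any chance occurrences)
  found <- find_motif_sites(g, "CCTCAGC")
  expect_true(all(g$motifs$start %in% found$start[found$strand == "+"]))
})

test_that("motif scanning agrees with an independent string-scan oracle", {
  g <- make_genome(c(chrA = 30000L, chrB = 20000L), gc = 0.5, seed = 3)
  for (motif in c("GCGATCGC", "CCTCAGC")) {
    found <- count_motif_sites(g, motif)
    oracle <- 0L
    pal <- identical(motif, oracle_rc(motif))
    for (chrom in names(g$sequences)) {
      s <- g$sequences[[chrom]]
      hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
      oracle <- oracle + sum(hits > 0)
      if (!pal) {
        hits_rc <- gregexpr(oracle_rc(motif), s, fixed = TRUE)[[1]]
        oracle <- oracle + sum(hits_rc > 0)
      }
    }
    expect_identical(found, oracle)
  }
})

test_that("overlapping planted features are rejected with the colliding intervals named", {
  expect_error(
    make_genome(c(chrA = 10000L),
                motifs = data.frame(chrom = "chrA", start = c(100L, 103L),
                                    strand = "+", motif = "CCTCAGC"),
                seed = 1),
    "collides")
})

test_that("explicit break lists are reproduced verbatim and bounds are checked", {
  g <- tiny_genome()
  tr <- simulate_breaks(g, breaks = data.frame(chrom = "chrA", pos = 5000L,
                                               strand = "+"))
  expect_identical(tr$breaks,
                   data.frame(chrom = "chrA", pos = 5000L, strand = "+",
                              stringsAsFactors = FALSE))
  expect_error(simulate_breaks(g, breaks = data.frame(chrom = "chrA",
                                                      pos = 70000L,
                                                      strand = "+")),
               "out of bounds")
})

test_that("random break placement covers both strands, stays in bounds, and is seed-deterministic", {
  g <- make_genome(c(chrA = 100000L), gc = 0.41, seed = 5)
  tr <- simulate_breaks(g, n = 1000L, seed = 6)
  expect_equal(nrow(tr$breaks), 1000L)
  expect_true(all(tr$breaks$pos >= 0 & tr$breaks$pos < 100000L))
  expect_setequal(unique(tr$breaks$strand), c("+", "-"))
  tr2 <- simulate_breaks(g, n = 1000L, seed = 6)
  expect_identical(tr$breaks, tr2$breaks)
  expect_error(simulate_breaks(g, n = 10^7, seed = 1), "eligible")
})

test_that("per-element relative rates produce the closed-form inside fraction", {
  ## element covering ~10% of eligible positions at 3x rate:
  ## expected inside fraction = 3*0.1 / (3*0.1 + 0.9) = 0.25
  g <- make_genome(c(chrA = 200000L), gc = 0.41, seed = 7)
  elig <- breakome:::break_eligibility(g)
  n_elig <- sum(elig$chrA$plus) + sum(elig$chrA$minus)
  ## choose the element so it covers 10% of *eligible* positions
  pos_elig <- sort(c(which(elig$chrA$plus), which(elig$chrA$minus)))
  cut <- stats::quantile(pos_elig, 0.1, type = 1)
  el <- data.frame(chrom = "chrA", start = 0L, end = as.integer(cut))
  g$elements <- list(el = el)
  frac_elig <- mean(pos_elig <= cut)
  p_expected <- 3 * frac_elig / (3 * frac_elig + (1 - frac_elig))
  n <- 10000L
  tr <- simulate_breaks(g, n = n, element_rates = list(el = 3), seed = 8)
  inside <- tr$breaks$pos < el$end
  ## 99% binomial interval around the expectation
  se <- sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(mean(inside) - p_expected), 2.58 * se + 0.01)
})

test_that("ILM reads match the independent chemistry oracle on both strands", {
  g <- tiny_genome()
  tr <- simulate_breaks(g, n = 40L, seed = 9)
  cfg <- library_config("ILM", read_length = 50L, seed = 10)
  lib <- build_ilm_library(g, tr, cfg)
  expect_equal(nrow(lib$read2), 40L)
  for (i in seq_len(40)) {
    b <- tr$breaks[i, ]
    expect_identical(lib$read2$seq[i],
                     oracle_ilm_read2(g, b$chrom, b$pos, b$strand, 50L),
                     label = sprintf("read2 for break %d (%s)", i, b$strand))
    expect_true(startsWith(lib$read1$seq[i], strrep("G", 10)))
  }
})

test_that("explicit worked case: error-free '+' break, read 2 is 12 T's plus revcomp window", {
  g <- tiny_genome()
  tr <- simulate_breaks(g, breaks = data.frame(chrom = "chrA", pos = 5000L,
                                               strand = "+"))
  lib <- build_ilm_library(g, tr, library_config("ILM", read_length = 50L, seed = 1))
  want <- paste0(strrep("T", 12),
                 oracle_rc(substr(g$sequences$chrA, 4964L, 5001L)))  # 0b [4963,5001)
  expect_identical(lib$read2$seq[1], want)
})

test_that("SMS reads match the oracle, skip the break base, and respect the length range", {
  g <- tiny_genome()
  tr <- simulate_breaks(g, n = 40L, seed = 11)
  lib <- build_sms_library(g, tr, library_config("SMS", seed = 12))
  lens <- nchar(lib$reads$seq)
  expect_true(all(lens >= 25 & lens <= 60))
  for (i in seq_len(40)) {
    b <- tr$breaks[i, ]
    expect_identical(lib$reads$seq[i],
                     oracle_sms_read(g, b$chrom, b$pos, b$strand, lens[i]))
  }
  ## fixed-length worked case: window excludes the break base
  tr1 <- simulate_breaks(g, breaks = data.frame(chrom = "chrA", pos = 5000L,
                                                strand = "+"))
  lib1 <- build_sms_library(g, tr1, library_config("SMS",
                                                   sms_length_range = c(30L, 30L),
                                                   seed = 1))
  expect_identical(lib1$reads$seq[1],
                   oracle_rc(substr(g$sequences$chrA, 4971L, 5000L)))  # 0b [4970,5000)
})

test_that("untailed libraries emit no break-derived reads; channels conserve", {
  g <- tiny_genome()
  tr <- simulate_breaks(g, n = 30L, seed = 13)
  lib <- build_ilm_library(g, tr, library_config("ILM", tailed = FALSE,
                                                 n_artifacts = 15L, seed = 14))
  expect_false(any(lib$origin == "break"))
  expect_equal(sum(lib$origin == "artifact"), 15L)
  expect_equal(length(lib$origin), nrow(lib$read2))
  ## empty everything -> empty FASTQ
  tr0 <- simulate_breaks(g, breaks = data.frame(chrom = character(0),
                                                pos = integer(0),
                                                strand = character(0)))
  lib0 <- build_sms_library(g, tr0, library_config("SMS", seed = 1))
  expect_equal(nrow(lib0$reads), 0L)
})

test_that("libraries are byte-identical across runs with the same config and seed", {
  g <- tiny_genome()
  tr <- simulate_breaks(g, n = 25L, seed = 15)
  cfg <- library_config("ILM", n_artifacts = 5L, error_rate = 0.01, seed = 16)
  l1 <- build_ilm_library(g, tr, cfg)
  l2 <- build_ilm_library(g, tr, cfg)
  expect_identical(l1$read1, l2$read1)
  expect_identical(l1$read2, l2$read2)
  expect_identical(l1$origin, l2$origin)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(l1$read2, f1); write_fastq(l2$read2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("artifact reads carry a T-rich upstream alignment context", {
  g <- tiny_genome()
  tr <- simulate_breaks(g, n = 10L, seed = 17)
  lib <- build_ilm_library(g, tr, library_config("ILM", n_artifacts = 10L,
                                                 seed = 18))
  art <- lib$truth$artifact_sites
  for (i in seq_len(nrow(art))) {
    ## read 2 aligns '-' ending at the apparent break + 1; upstream 20-mer on
    ## the alignment strand is revcomp of the next 20 genomic bases
    win <- oracle_rc(substr(g$sequences[[art$chrom[i]]],
                            art$pos[i] + 2L, art$pos[i] + 21L))
    expect_gte(oracle_t_fraction(win), 0.45)
  }
})

test_that("FASTQ round-trips through files preserve reads and qualities", {
  g <- tiny_genome()
  tr <- simulate_breaks(g, n = 8L, seed = 19)
  lib <- build_sms_library(g, tr, library_config("SMS", seed = 20))
  f <- tempfile(fileext = ".fastq")
  write_fastq(lib$reads, f)
  back <- read_fastq(f)
  expect_identical(back$seq, lib$reads$seq)
  expect_identical(back$qual, lib$reads$qual)
  expect_identical(back$id, lib$reads$id)
})
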