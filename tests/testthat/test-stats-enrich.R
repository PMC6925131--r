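bg_100k <- data.frame(chrom = "chrA", start = 0L, end = 100000L)
el_10pc <- data.frame(chrom = "chrA", start = 0L, end = 10000L)

test_that("odds ratio is exactly 1 when the hit fraction equals the length fraction", {
  bs <- manual_breakset("chrA", c(seq(500L, 9500L, length.out = 10L),
                                  seq(10500L, 99000L, length.out = 90L)),
                        rep("+", 100L))
  res <- element_enrichment(bs, el_10pc, bg_100k)
  expect_equal(res$k, 10L)
  expect_equal(res$odds_ratio, 1.0)
})

test_that("k = n gives an infinite odds ratio and the exact two-sided binomial p", {
  bs <- manual_breakset("chrA", seq(100L, 9000L, length.out = 10L), rep("+", 10L))
  el_half <- data.frame(chrom = "chrA", start = 0L, end = 50000L)
  res <- element_enrichment(bs, el_half, bg_100k)
  expect_equal(res$odds_ratio, Inf)
  expect_equal(res$p_value, 2 * 0.5^10)   # 0.001953125, exact enumeration
  expect_equal(res$p_value, 0.001953125)
})

test_that("hit counting matches a brute-force scan on random instances", {
  set.seed(50)
  for (rep_i in 1:20) {
    n_iv <- sample(5:50, 1)
    ivs <- data.frame(chrom = "chrA", start = sort(sample(0:90000, n_iv)))
    ivs$end <- ivs$start + sample(100:1000, n_iv, replace = TRUE)
    bs <- random_breakset(sample(100:500, 1), seed = 50 + rep_i)
    res <- element_enrichment(bs, ivs, bg_100k)
    ## oracle over the merged element set
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges("chrA",
            IRanges::IRanges(ivs$start + 1L, ivs$end)))
    merged <- data.frame(chrom = "chrA",
                         start = GenomicRanges::start(gr) - 1L,
                         end = GenomicRanges::end(gr))
    merged$end <- pmin(merged$end, 100000L)
    k_oracle <- sum(oracle_in_intervals(bs$calls$chrom, bs$calls$start, merged))
    expect_equal(res$k, k_oracle)
  }
})

test_that("uniform breaks are calibrated (OR near 1) and planted 3x enrichment is detected", {
  g <- make_genome(c(chrA = 1000000L), gc = 0.41, seed = 51)
  el <- data.frame(chrom = "chrA", start = 100000L, end = 199800L)
  g$elements <- list(el = el)
  bg <- data.frame(chrom = "chrA", start = 1000L, end = 999000L)
  ## eligibility-free placement so rates are exactly uniform over background
  tr <- simulate_breaks(g, n = 10000L, seed = 52, require_non_a = FALSE,
                        avoid_priming = FALSE, margin = 1000L)
  bs <- manual_breakset(tr$breaks$chrom, tr$breaks$pos, tr$breaks$strand)
  res <- element_enrichment(bs, el, bg)
  expect_gt(res$odds_ratio, 0.9)
  expect_lt(res$odds_ratio, 1.1)

  tr3 <- simulate_breaks(g, n = 10000L, seed = 53, element_rates = list(el = 3),
                         require_non_a = FALSE, avoid_priming = FALSE,
                         margin = 1000L)
  bs3 <- manual_breakset(tr3$breaks$chrom, tr3$breaks$pos, tr3$breaks$strand)
  res3 <- element_enrichment(bs3, el, bg)
  expect_lt(res3$p_value, 0.01)
  expect_true(res3$ci95[1] < 3 && 3 < res3$ci95[2])
})

test_that("degenerate element lengths raise errors", {
  bs <- manual_breakset("chrA", 100L, "+")
  expect_error(element_enrichment(bs, data.frame(chrom = "chrA", start = 0L,
                                                 end = 0L), bg_100k))
  expect_error(element_enrichment(bs, bg_100k, bg_100k))
})

test_that("strand asymmetry counts template vs non-template per region class", {
  ## '+' gene: template breaks are on '-'
  regions <- data.frame(chrom = "chrA", start = c(0L, 1000L),
                        end = c(1000L, 2000L), gene_strand = "+",
                        class = c("exon", "intron"))
  bs <- manual_breakset("chrA",
                        c(10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L,
                          1500L, 1600L),
                        c(rep("-", 6), rep("+", 3), "-", "+"))
  res <- strand_asymmetry(bs, regions)
  exon <- res[res$class == "exon", ]
  expect_equal(exon$template, 6L)
  expect_equal(exon$nontemplate, 3L)
  expect_equal(exon$ratio, 2.0)
  intron <- res[res$class == "intron", ]
  expect_equal(intron$ratio, 1.0)
})

test_that("regions of genes annotated on both strands are excluded by default", {
  regions <- data.frame(chrom = "chrA", start = c(0L, 500L, 5000L),
                        end = c(1000L, 1500L, 6000L),
                        gene_strand = c("+", "-", "+"),
                        class = "exon")
  bs <- manual_breakset("chrA", c(700L, 5500L), c("-", "-"))
  res <- strand_asymmetry(bs, regions)
  ## the break at 700 sits in the ambiguous overlap and is not counted
  expect_equal(res$template[res$class == "exon"], 1L)
})

test_that("random gene models agree with a brute-force per-break classification", {
  set.seed(54)
  starts <- seq(0L, 90000L, by = 3000L)
  regions <- data.frame(chrom = "chrA", start = starts, end = starts + 2000L,
                        gene_strand = sample(c("+", "-"), length(starts), TRUE),
                        class = sample(c("exon", "intron"), length(starts), TRUE))
  bs <- random_breakset(800L, seed = 55)
  res <- strand_asymmetry(bs, regions)
  for (cl in unique(regions$class)) {
    t_cnt <- 0L; nt_cnt <- 0L
    for (i in seq_len(nrow(bs$calls))) {
      for (j in which(regions$class == cl)) {
        if (bs$calls$start[i] >= regions$start[j] &&
            bs$calls$start[i] < regions$end[j]) {
          if (bs$calls$strand[i] != regions$gene_strand[j]) t_cnt <- t_cnt + 1L
          else nt_cnt <- nt_cnt + 1L
        }
      }
    }
    expect_equal(res$template[res$class == cl], t_cnt)
    expect_equal(res$nontemplate[res$class == cl], nt_cnt)
  }
})

test_that("symmetric simulated breaks give exon and intron ratios near 1", {
  set.seed(56)
  starts <- seq(0L, 95000L, by = 2000L)
  regions <- data.frame(chrom = "chrA", start = starts, end = starts + 1500L,
                        gene_strand = sample(c("+", "-"), length(starts), TRUE),
                        class = rep(c("exon", "intron"), length.out = length(starts)))
  bs <- random_breakset(4000L, seed = 57)   # strands i.i.d. fair coin
  res <- strand_asymmetry(bs, regions)
  for (cl in c("exon", "intron")) {
    row <- res[res$class == cl, ]
    n <- row$template + row$nontemplate
    ## binomial sampling band for the template fraction around 1/2
    phat <- row$template / n
    expect_lt(abs(phat - 0.5), 2.58 * sqrt(0.25 / n))
  }
})

test_that("variant overlap respects window boundaries and matches the all-pairs oracle", {
  vars <- data.frame(chrom = "chrA", pos = 500L)
  bs_at <- manual_breakset("chrA", 500L, "+")
  res0 <- variant_overlap(bs_at, vars, windows = 0L, background_length = 1e5)
  expect_equal(res0$k, 1L)

  bs_3 <- manual_breakset("chrA", 503L, "+")
  r <- variant_overlap(bs_3, vars, windows = c(2L, 5L), background_length = 1e5)
  expect_equal(r$k[r$window == 2], 0L)
  expect_equal(r$k[r$window == 5], 1L)

  set.seed(58)
  vars_r <- data.frame(chrom = "chrA", pos = sample(0:99999, 300L))
  bs_r <- random_breakset(400L, seed = 59)
  for (w in c(0L, 2L, 5L, 10L)) {
    got <- variant_overlap(bs_r, vars_r, windows = w, background_length = 1e5)
    k_oracle <- sum(vapply(bs_r$calls$start, function(p) {
      any(abs(vars_r$pos - p) <= w)
    }, logical(1)))
    expect_equal(got$k, k_oracle)
  }
})

test_that("allele-frequency classes follow the stated thresholds", {
  expect_identical(variant_af_class(c(0.5, 0.05, 0.049, 0.005, 0.004)),
                   c("common", "common", "low_frequency", "low_frequency",
                     "rare"))
  expect_error(variant_af_class(1.2), "must be in")
})

test_that("position-set overlap uses the exact one-sided hypergeometric tail", {
  a <- data.frame(chrom = "chrA", pos = 1:5)
  b <- data.frame(chrom = "chrA", pos = 1:5)
  res <- position_overlap_test(a, b, universe_size = 20L)
  expect_equal(res$overlap, 5L)
  expect_equal(res$p_value, 1 / choose(20, 5))
})

test_that("variants load from VCF with types and AF classes", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##contig=<ID=chrA,length=100000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrA\t101\t.\tA\tG\t50\tPASS\tAF=0.2",
    "chrA\t500\t.\tAT\tA\t50\tPASS\tAF=0.01",
    "chrA\t900\t.\tC\tT\t50\tPASS\tAF=0.001"), vcf)
  v <- read_variants_vcf(vcf)
  expect_equal(v$pos, c(100L, 499L, 899L))   # 1-based VCF -> 0-based
  expect_identical(v$type, c("SNP", "indel", "SNP"))
  expect_identical(v$class, c("common", "low_frequency", "rare"))
})
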