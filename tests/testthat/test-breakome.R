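genes2 <- data.frame(gene = c("gA", "gB"), chrom = "chrA",
                     start = c(1000L, 10000L), end = c(2000L, 14000L))

test_that("gene density follows the per-kb per-million-breaks formula", {
  ## 5 '+' breaks in a 1-kb gene, 1000 total breaks -> 5000
  pos <- c(seq(1100L, 1900L, length.out = 5L), seq(20000L, 90000L, length.out = 995L))
  bs <- manual_breakset("chrA", as.integer(pos),
                        c(rep("+", 5), rep("-", 995)))
  bm <- gene_density_matrix(list(s1 = bs), genes2)
  expect_equal(bm$matrix["s1", "gA|+"], 5 / (1 * 1000) * 1e6)
  expect_equal(bm$matrix["s1", "gA|+"], 5000)
  expect_equal(bm$matrix["s1", "gA|-"], 0)
  expect_equal(ncol(bm$matrix), 2L * nrow(genes2))
})

test_that("a sample with no genic breaks yields an all-zero row", {
  bs <- manual_breakset("chrA", c(50000L, 60000L), c("+", "-"))
  bm <- gene_density_matrix(list(s = bs), genes2)
  expect_true(all(bm$matrix == 0))
})

test_that("densities are invariant under read-count duplication of a sample", {
  bs1 <- manual_breakset("chrA", c(1100L, 1200L, 50000L), rep("+", 3),
                         read_count = c(1L, 1L, 1L))
  bs2 <- manual_breakset("chrA", c(1100L, 1200L, 50000L), rep("+", 3),
                         read_count = c(7L, 7L, 7L))
  m1 <- gene_density_matrix(list(s = bs1), genes2)$matrix
  m2 <- gene_density_matrix(list(s = bs2), genes2)$matrix
  expect_equal(m1, m2)
})

test_that("matrix cells equal a brute-force per-break assignment", {
  set.seed(90)
  gs <- seq(0L, 90000L, by = 10000L)
  genes <- data.frame(gene = sprintf("g%02d", seq_along(gs)), chrom = "chrA",
                      start = gs, end = gs + sample(2000:8000, length(gs), TRUE))
  samples <- list(a = random_breakset(400L, seed = 91),
                  b = random_breakset(300L, seed = 92))
  bm <- gene_density_matrix(samples, genes)
  for (snm in names(samples)) {
    cc <- samples[[snm]]$calls
    for (gi in seq_len(nrow(genes))) {
      for (str in c("+", "-")) {
        cnt <- sum(cc$start >= genes$start[gi] & cc$start < genes$end[gi] &
                     cc$strand == str)
        want <- cnt / ((genes$end[gi] - genes$start[gi]) / 1000 * nrow(cc)) * 1e6
        expect_equal(bm$matrix[snm, paste(genes$gene[gi], str, sep = "|")],
                     want)
      }
    }
  }
})

test_that("PCA separates two simulated groups and is sane on duplicates", {
  set.seed(93)
  base <- matrix(rexp(20 * 40), nrow = 20)
  shift <- matrix(0, 20, 40); shift[11:20, 1:10] <- 3   # group-specific genes
  m <- base + shift
  rownames(m) <- sprintf("s%02d", 1:20)
  colnames(m) <- sprintf("g%02d|%s", rep(1:20, each = 2), c("+", "-"))
  emb <- pca_embed(m, n_components = 3L)
  expect_true(all(diff(emb$explained_variance) <= 0))
  expect_lte(sum(emb$explained_variance), 1)
  ## silhouette of the two groups on PC1
  pc1 <- emb$coordinates[, 1]
  grp <- rep(c(1, 2), each = 10)
  sil <- vapply(seq_along(pc1), function(i) {
    a <- mean(abs(pc1[i] - pc1[grp == grp[i] & seq_along(pc1) != i]))
    b <- mean(abs(pc1[i] - pc1[grp != grp[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  ## duplicated rows embed identically
  m2 <- rbind(m, dup = m[1, ])
  emb2 <- pca_embed(m2, n_components = 2L)
  expect_equal(unname(emb2$coordinates["dup", ]),
               unname(emb2$coordinates["s01", ]))

  expect_warning(pca_embed(m[1:3, ], n_components = 10L), "truncating")
})

features_fixture <- function(seed, n = 66L) {
  set.seed(seed)
  f <- matrix(rnorm(n * 4), nrow = n,
              dimnames = list(NULL, c("f1", "f2", "f3", "f4")))
  f
}

test_that("a perfectly ordered feature gives AUC 1 and a null model gives pseudo-R2 0", {
  f <- features_fixture(94)
  labels <- factor(ifelse(f[, "f1"] > 0, "old", "young"),
                   levels = c("young", "old"))
  fit <- fit_age_classifier(f, labels)
  expect_equal(fit$auc, 1.0)
  expect_true(fit$separation_flagged)
  expect_gte(fit$accuracy, 0.95)

  ## intercept-only data: pseudo-R2 = 0 by definition
  f0 <- matrix(0, nrow = 66, ncol = 1, dimnames = list(NULL, "f"))
  labels0 <- factor(rep(c("young", "old"), 33))
  fit0 <- suppressWarnings(fit_age_classifier(f0, labels0))
  expect_equal(fit0$pseudo_r2, 0, tolerance = 1e-8)
})

test_that("permuted labels give chance-level AUC out of fold", {
  f <- features_fixture(95)
  set.seed(96)
  aucs <- vapply(1:100, function(i) {
    labels <- factor(sample(rep(c("young", "old"), 33)),
                     levels = c("young", "old"))
    suppressWarnings(fit_age_classifier(f, labels, folds = 5L, seed = i))$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("classifier recovers planted coefficient signs under moderate noise", {
  ok <- 0L
  for (s in 1:20) {
    f <- features_fixture(200 + s)
    lin <- 1.5 * f[, "f1"] - 1.5 * f[, "f2"] + rnorm(66, sd = 1)
    labels <- factor(ifelse(lin > 0, "old", "young"), levels = c("young", "old"))
    fit <- suppressWarnings(fit_age_classifier(f, labels))
    cf <- coef(fit)
    if (cf["f1"] > 0 && cf["f2"] < 0) ok <- ok + 1L
  }
  expect_gte(ok, 18L)   # >= 90% of runs
})

test_that("ages exactly linear in one feature give r = 1; permuted ages give r near 0", {
  f <- features_fixture(97)
  ages <- 40 + 10 * f[, "f2"]
  fit <- suppressWarnings(fit_age_regressor(f, ages))  # noise-free: lm warns
  expect_equal(fit$pearson_r, 1.0)
  expect_lt(fit$p_value, 1e-10)

  set.seed(98)
  rs <- vapply(1:100, function(i) {
    a <- sample(20:80, 66, replace = TRUE)
    cor(fitted(lm(a ~ f)), a)
  }, numeric(1))
  ## fitted-vs-true r is non-negative; under the null it stays small
  expect_lt(mean(rs), 0.35)
})

test_that("regressor recovers a planted signal-to-noise of R2 = 0.5 at n = 66", {
  r2s <- vapply(1:30, function(s) {
    f <- features_fixture(300 + s)
    signal <- f[, "f1"] + f[, "f3"]
    ## Var(signal) = 2; choose noise so theoretical R2 = 0.5
    ages <- 50 + signal + rnorm(66, sd = sqrt(2))
    fit_age_regressor(f, ages)$pearson_r^2
  }, numeric(1))
  expect_gt(mean(r2s), 0.35)
  expect_lt(mean(r2s), 0.65)

  expect_error(fit_age_regressor(features_fixture(1), rep(50, 66)),
               "distinct")
})

test_that("sample features assemble the 8-feature vector consistently with the stats module", {
  set.seed(99)
  ann <- list(
    exon = data.frame(chrom = "chrA", start = 10000L, end = 20000L),
    intron = data.frame(chrom = "chrA", start = 20000L, end = 30000L),
    promoter = data.frame(chrom = "chrA", start = 30000L, end = 35000L),
    insulator = data.frame(chrom = "chrA", start = 40000L, end = 45000L),
    enhancer = data.frame(chrom = "chrA", start = 50000L, end = 55000L),
    background = data.frame(chrom = "chrA", start = 0L, end = 100000L),
    conservation = signal_track(data.frame(chrom = "chrA", start = 0L,
                                           end = 100000L, value = 0.5)),
    chrM = "chrM")
  bs <- random_breakset(500L, seed = 100)
  sf <- sample_features(bs, ann)
  expect_length(sf, 8L)
  expect_true(all(is.finite(sf)))
  expect_equal(unname(sf["or_exon"]),
               element_enrichment(bs, ann$exon, ann$background)$odds_ratio)
  expect_equal(unname(sf["phylop_positive"]), 0.5)
  expect_equal(unname(sf["phylop_negative_abs"]), 0)
  expect_equal(unname(sf["chrM_fraction"]), 0)

  ## all breaks on chrM -> fraction 1
  bsm <- manual_breakset("chrM", c(100L, 200L), c("+", "-"))
  ann_m <- ann
  ann_m$background <- data.frame(chrom = c("chrA", "chrM"),
                                 start = 0L, end = c(100000L, 16000L))
  expect_equal(unname(suppressWarnings(sample_features(bsm, ann_m))["chrM_fraction"]),
               1)

  expect_error(sample_features(bs, ann[-1]), "missing annotation")
})
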