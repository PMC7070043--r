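test_that("the hurdle test is symmetric and null under identical groups", {
  set.seed(12)
  vals <- rexp(40)
  mat <- rbind(g1 = c(vals, vals))
  nm <- as_norm(mat)
  r <- hurdle_test(nm, 1:40, 41:80, "g1")
  expect_lt(r$lrt, 1e-8)
  expect_gt(r$p, 0.999)
  expect_equal(r$log2fc, 0)

  # swapping group labels flips the sign, keeps the p-value
  set.seed(13)
  mat2 <- rbind(g1 = c(rexp(40), rexp(40) + 0.5))
  nm2 <- as_norm(mat2)
  ra <- hurdle_test(nm2, 1:40, 41:80, "g1")
  rb <- hurdle_test(nm2, 41:80, 1:40, "g1")
  expect_equal(ra$p, rb$p, tolerance = 1e-12)
  expect_equal(ra$log2fc, -rb$log2fc, tolerance = 1e-12)
  expect_equal(ra$direction, -rb$direction)
})

test_that("fully detected location shifts reduce to the Gaussian LRT oracle", {
  set.seed(21)
  a <- rnorm(400, 3, 0.8)
  b <- a + 1.0
  mat <- rbind(g1 = c(a, b))
  nm <- as_norm(mat)
  r <- hurdle_test(nm, 1:400, 401:800, "g1")
  expect_lt(r$p, 1e-6)

  # independent oracle: two-sample Gaussian LRT via lm deviances; the
  # detection component contributes nothing when detection is 100%/100%
  y <- c(a, b); grp <- factor(rep(c("A", "B"), each = 400))
  rss0 <- sum(resid(lm(y ~ 1))^2)
  rss1 <- sum(resid(lm(y ~ grp))^2)
  lrt_oracle <- length(y) * log(rss0 / rss1)
  expect_equal(r$lrt, lrt_oracle, tolerance = 1e-8)
  expect_equal(r$p, pchisq(lrt_oracle, 2, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("degenerate detection patterns fall back gracefully", {
  # gene undetected in both groups: untestable, p = 1, logFC = 0
  mat <- rbind(g1 = rep(0, 20))
  r <- hurdle_test(as_norm(mat), 1:10, 11:20, "g1")
  expect_true(r$untestable)
  expect_equal(r$p, 1)
  expect_equal(r$log2fc, 0)

  # < 2 expressing cells in one group: discrete component only, df = 1
  mat2 <- rbind(g1 = c(rep(0, 9), 2.0, rexp(10) + 0.5))
  r2 <- hurdle_test(as_norm(mat2), 1:10, 11:20, "g1")
  expect_equal(r2$df, 1L)
  expect_true(is.finite(r2$lrt) && r2$p <= 1)
})

test_that("type-I error is controlled on null genes", {
  set.seed(77)
  n <- 800; nc <- 120
  # zero-inflated lognormal null: same law in both groups
  det_p <- runif(n, 0.3, 0.9)
  mk <- function() {
    m <- matrix(rlnorm(n * nc, 1, 0.4), n, nc) *
      matrix(rbinom(n * nc, 1, det_p), n, nc)
    m
  }
  mat <- cbind(mk(), mk())
  rownames(mat) <- sprintf("g%04d", 1:n)
  nm <- as_norm(mat)
  res <- hurdle_test_all(nm, 1:nc, (nc + 1):(2 * nc))
  fp <- mean(res$p < 0.05)
  expect_gt(fp, 0.02)
  expect_lt(fp, 0.09)
  # and essentially nothing survives the DEG cutoffs
  called <- call_degs(res)
  expect_lt(length(called$degs), n * 0.005 + 3)
})

test_that("DEG calling applies the published cutoffs and BH step-up", {
  # hand-computed Benjamini-Hochberg on the printed 5-p-value example:
  # sorted p * n/rank = .005 .005 .0333 .625 .9 after step-up
  de <- structure(data.frame(
    gene = paste0("g", 1:5),
    log2fc = c(1, -1, 2, 0.5, -2),
    detection_a = rep(0.5, 5), detection_b = rep(0.5, 5),
    n_a = rep(100L, 5), n_b = rep(100L, 5),
    lrt = rep(10, 5), df = rep(2L, 5),
    p = c(0.001, 0.002, 0.02, 0.5, 0.9),
    direction = c(1L, -1L, 1L, 1L, -1L),
    untestable = rep(FALSE, 5), stringsAsFactors = FALSE),
    class = c("dex_de", "data.frame"))
  out <- call_degs(de, alpha = 0.05)
  expect_equal(out$table$padj,
               c(0.005, 0.005, 0.02 * 5 / 3, 0.625, 0.9),
               tolerance = 1e-12)

  # detection below 10% in both groups is excluded before testing
  de$detection_a <- c(0.09, rep(0.5, 4))
  de$detection_b <- c(0.09, rep(0.5, 4))
  out2 <- call_degs(de)
  expect_false("g1" %in% out2$table$gene)
  expect_equal(out2$n_tested, 4L)
  # ...but 10% in one group suffices under the "either" scope
  de$detection_b <- c(0.10, rep(0.5, 4))
  expect_true("g1" %in% call_degs(de)$table$gene)

  # fold change exactly at the cutoff is retained
  de3 <- de
  de3$detection_a <- rep(0.5, 5)
  de3$log2fc <- c(log2(1.25), log2(1.249), 2, 2, 2)
  de3$p <- c(1e-8, 1e-8, 1e-8, 0.5, 0.9)
  out3 <- call_degs(de3)
  expect_true("g1" %in% out3$degs)
  expect_false("g2" %in% out3$degs)
})

test_that("DEG power is high for strong effects at full design size", {
  cfg <- sim_config(n_genes = 1000, frac_deg = 0.03, frac_down = 0.25,
                    timepoints = c("0h", "18h"), time_hours = c(0, 18),
                    responder_prob = c(0, 0.5), cells_per_timepoint = 400,
                    fold_change_range = c(4, 6),
                    baseline_logmean_range = c(0, 2),
                    dropout_midpoint = -2, dropout_slope = 2, seed = 31)
  tr <- build_truth(cfg)
  tr$genes$kinetic[tr$genes$is_deg] <- "early"
  sim <- simulate_counts(tr, cfg)
  nm <- normalize_log(sim)
  de <- de_by_timepoint(nm)
  truth_degs <- tr$genes$gene_id[tr$genes$is_deg]
  recall <- mean(truth_degs %in% de[["18h"]]$degs)
  expect_gt(recall, 0.9)
  # false discoveries stay near the nominal FDR
  fdr <- mean(!(de[["18h"]]$degs %in% truth_degs))
  expect_lt(fdr, 0.05)
})

test_that("superset merging keeps provenance and consensus direction", {
  mk <- function(genes, lfc) {
    list(degs = genes,
         table = data.frame(gene = genes, log2fc = lfc,
                            direction = ifelse(lfc >= 0, 1L, -1L),
                            deg = TRUE, stringsAsFactors = FALSE))
  }
  ss <- merge_supersets(list(`1h` = mk(c("a", "b"), c(0.5, 1)),
                             `2h` = mk(c("b", "c"), c(-2, 0.7))))
  expect_setequal(ss$gene, c("a", "b", "c"))
  b <- ss[ss$gene == "b", ]
  expect_equal(b$n_timepoints, 2L)
  expect_equal(b$direction, -1L)        # from the max |logFC| timepoint
  expect_equal(b$timepoints, "1h,2h")

  ov <- deg_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$shared, 2L)
  expect_equal(ov$unique_a, 1L)
  expect_equal(ov$unique_b, 1L)
  expect_equal(ov$shared + ov$unique_a, 3L)   # conservation
})

test_that("peak proximity matches the all-pairs oracle with boundaries", {
  tss <- data.frame(chrom = "chr1", pos = 100000L, strand = "+",
                    gene_id = "gX", stringsAsFactors = FALSE)
  # nearest peak edge exactly at the 50 kb boundary -> proximal
  pk_edge <- data.frame(chrom = "chr1", start = 150000L, end = 150300L)
  expect_equal(unname(peak_proximity(tss, pk_edge)), 1L)
  pk_beyond <- data.frame(chrom = "chr1", start = 150001L, end = 150300L)
  expect_equal(unname(peak_proximity(tss, pk_beyond)), 0L)
  # upstream boundary: last covered base at pos - 50000
  pk_up <- data.frame(chrom = "chr1", start = 49700L, end = 50001L)
  expect_equal(unname(peak_proximity(tss, pk_up)), 1L)
  pk_up2 <- data.frame(chrom = "chr1", start = 49700L, end = 50000L)
  expect_equal(unname(peak_proximity(tss, pk_up2)), 0L)
  # TSS inside a peak: distance zero
  pk_in <- data.frame(chrom = "chr1", start = 99900L, end = 100100L)
  expect_equal(unname(peak_proximity(tss, pk_in)), 1L)
  # no peaks on the chromosome
  pk_other <- data.frame(chrom = "chr2", start = 99900L, end = 100100L)
  expect_equal(unname(peak_proximity(tss, pk_other)), 0L)
  expect_error(peak_proximity(tss, data.frame(chrom = "chr1", start = 10L,
                                              end = 10L)), "malformed")

  set.seed(91)
  n_conf <- 200
  for (i in seq_len(n_conf)) {
    tssr <- data.frame(chrom = sample(c("c1", "c2"), 8, TRUE),
                       pos = sample.int(500000L, 8), strand = "+",
                       gene_id = paste0("g", 1:8), stringsAsFactors = FALSE)
    pkr <- data.frame(chrom = sample(c("c1", "c2"), 12, TRUE),
                      start = sample.int(500000L, 12))
    pkr$end <- pkr$start + sample.int(5000L, 12)
    expect_identical(peak_proximity(tssr, pkr, window = 50000),
                     oracle_proximity(tssr, pkr, window = 50000))
  }
})
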