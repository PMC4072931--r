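test_that("merge_peaks unions, merges overlaps and book-ended intervals", {
  a <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200))
  b <- data.frame(chrom = "chr1", start = 200, end = 300)
  # disjoint sets kept; book-ended intervals merged
  m <- merge_peaks(list(data.frame(chrom = "chr1", start = 0, end = 100),
                        data.frame(chrom = "chr1", start = 200, end = 300)))
  expect_equal(m$start, c(0, 200))
  expect_equal(m$end, c(100, 300))
  m2 <- merge_peaks(list(data.frame(chrom = "chr1", start = 100, end = 200),
                         data.frame(chrom = "chr1", start = 150, end = 250)))
  expect_equal(m2[, c("start", "end")], data.frame(start = 100, end = 250))
  m3 <- merge_peaks(list(a, b))
  expect_equal(m3$start, 0)
  expect_equal(m3$end, 300)
  expect_error(merge_peaks(data.frame(chrom = "chr1", start = 10, end = 10)),
               "start >= end")
})

test_that("merge_peaks equals the brute-force per-bp union on random instances", {
  set.seed(11)
  for (rep in 1:20) {
    sets <- lapply(1:3, function(i) {
      s <- sort(sample.int(9000, 8))
      data.frame(chrom = sample(c("chrA", "chrB"), 8, TRUE),
                 start = s, end = s + sample.int(500, 8))
    })
    got <- merge_peaks(sets)[, c("chrom", "start", "end")]
    want <- brute_union(sets)
    got <- got[order(got$chrom, got$start), ]
    want <- want[order(want$chrom, want$start), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("accessibility normalization follows (c/L)/(R/G) and is depth-invariant", {
  peaks <- data.frame(peak_id = c("p1", "p2"), chrom = "chr1",
                      start = c(0, 1000), end = c(500, 1500))
  counts <- cbind(s1 = c(100, 999900), s2 = c(50, 100))
  A <- normalize_accessibility(counts, peaks, genome_size = 1e8)
  # c=100, L=500, R=1e6, G=1e8 -> (100/500)/(1e6/1e8) = 20
  expect_equal(A["p1", "s1"], 20)
  expect_equal(A["p1", "s2"][[1]], (50 / 500) / (150 / 1e8))
  # doubling a sample's counts leaves its column exactly unchanged
  A2 <- normalize_accessibility(cbind(s1 = 2 * counts[, 1], s2 = counts[, 2]), peaks, 1e8)
  expect_equal(A2[, "s1"], A[, "s1"], tolerance = 1e-15)
  expect_equal(normalize_accessibility(cbind(s1 = c(0, 10), s2 = c(1, 1)), peaks, 1e8)["p1", "s1"], 0)
  expect_error(normalize_accessibility(cbind(s1 = c(0, 0)), peaks[1:2, ], 1e8), "zero total")
})

test_that("quantile normalization maps columns onto the sorted-mean reference with tie averaging", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  q <- quantile_normalize(m)
  expect_equal(unname(q[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, "b"]), c(2.5, 3.5, 4.5))
  # a constant column receives the mean of the reference distribution
  m2 <- cbind(a = c(5, 5, 5), b = c(1, 2, 3))
  q2 <- quantile_normalize(m2)
  expect_equal(unname(q2[, "a"]), rep(3.5, 3))
  expect_equal(unname(q2[, "b"]), c(3, 3.5, 4))
  # identical distributions are left unchanged
  m3 <- cbind(a = c(3, 1, 2), b = c(1, 2, 3))
  expect_equal(quantile_normalize(m3), m3, ignore_attr = TRUE)
  expect_warning(quantile_normalize(cbind(a = 1:3)), ">= 2 samples")
})

test_that("quantile normalization is idempotent and agrees with limma on tie-free data", {
  set.seed(7)
  m <- matrix(rlnorm(200 * 6), 200, 6, dimnames = list(NULL, paste0("s", 1:6)))
  q1 <- quantile_normalize(m)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  ref <- sort(q1[, 1])
  for (j in 2:6) expect_equal(sort(q1[, j]), ref, tolerance = 1e-12)
  skip_if_not_installed("limma")
  expect_equal(unname(q1), unname(limma::normalizeQuantiles(m, ties = TRUE)),
               tolerance = 1e-10)
})

test_that("pair discordance computes D_abs and bounded D_norm", {
  pairing <- make_pairing(2)
  mat <- matrix(c(5, 3, 5, 1, 10, 2, 0, 2), nrow = 2,
                dimnames = list(c("pk1", "pk2"), pairing$sample_id))
  d <- pair_discordance(mat, pairing)
  g <- function(pk, pr) d[d$peak_id == pk & d$pair_id == pr, ]
  expect_equal(g("pk1", "p1")$d_abs, 0)
  expect_equal(g("pk1", "p1")$d_norm, 0)
  expect_equal(g("pk2", "p1")$d_abs, 2)   # X1=3, X2=1
  expect_equal(g("pk2", "p1")$d_norm, 0.5)
  expect_equal(g("pk1", "p2")$d_norm, 1)  # X1=10, X2=0
  set.seed(1)
  x1 <- rlnorm(10000); x2 <- rlnorm(10000)
  dn <- abs(x1 - x2) / (x1 + x2)
  mat2 <- rbind(x1, x2)  # sanity for the formula itself
  expect_true(all(dn >= 0 & dn <= 1))
  expect_true(all((dn == 0) == (x1 == x2)))
})

test_that("discordant-site calling implements the fold-change and variance rules", {
  pairing <- make_pairing(3)
  disc <- data.frame(peak_id = "pk", pair_id = c("p1", "p2", "p3"),
                     x1 = c(15, 5, 4), x2 = c(2, 5, 1))
  disc$d_abs <- abs(disc$x1 - disc$x2)
  disc$d_norm <- disc$d_abs / (disc$x1 + disc$x2)
  fc <- call_discordant_sites(disc, "fold_change", pseudocount = 1)
  expect_equal(fc$discordant, c(TRUE, FALSE, FALSE))  # 16/3 > 4; 1 < 4; 5/2 < 4
  # equal siblings never flagged under either rule
  eq <- disc; eq$x2 <- eq$x1
  expect_false(any(call_discordant_sites(eq, "fold_change")$discordant))
  # pairs internally identical but different between pairs: variance rule unflagged
  vr <- data.frame(peak_id = "pk", pair_id = c("p1", "p2", "p3"),
                   x1 = c(1, 5, 9), x2 = c(1, 5, 9))
  out <- call_discordant_sites(vr, "variance")
  expect_equal(out$within_var, 0)
  expect_false(out$discordant)
  expect_error(call_discordant_sites(disc, "nope"))
})

test_that("state summaries count domains and flagged fractions by overlap", {
  # 12 poised-promoter domains each holding one peak, 3 of them flagged
  states <- data.frame(chrom = "chr1", start = seq(0, 11000, 1000),
                       end = seq(500, 11500, 1000), name = "poised promoter")
  peaks <- data.frame(chrom = "chr1", start = states$start + 100,
                      end = states$start + 200,
                      value = 1:12, flagged = rep(c(TRUE, FALSE), c(3, 9)))
  s <- summarize_by_state(peaks, states)
  expect_equal(s$n_domains, 12L)
  expect_equal(s$fraction_flagged, 0.25)
  expect_equal(s$mean, mean(1:12))
  # a peak overlapping two states contributes to both
  st2 <- data.frame(chrom = "chr1", start = c(0, 100), end = c(150, 300),
                    name = c("A", "B"))
  pk2 <- data.frame(chrom = "chr1", start = 120, end = 140, value = 7)
  s2 <- summarize_by_state(pk2, st2)
  expect_equal(sort(s2$state), c("A", "B"))
  expect_equal(s2$mean, c(7, 7))
  suppressWarnings(expect_warning(
    summarize_by_state(data.frame(chrom = "chr2", start = 1, end = 2, value = 1), st2),
    "no peak overlaps"))
})

test_that("group comparison of discordance recovers planted shifts and orderings", {
  set.seed(42)
  base <- pmin(1, pmax(0, rnorm(200, 0.3, 0.05)))
  shifted <- pmin(1, pmax(0, rnorm(200, 0.5, 0.05)))
  r <- compare_discordance_by_group(c(base, shifted),
                                    rep(c("no_mutation", "mutation"), each = 200))
  expect_lt(r$tests$p[r$tests$group == "no_mutation"], 1e-6)
  # identical groups: p ~ 1, equal means
  r2 <- compare_discordance_by_group(c(base, base), rep(c("a", "b"), each = 200))
  expect_gt(r2$tests$p, 0.9)
  expect_equal(unname(r2$means[1]), unname(r2$means[2]))
  # planted monotone strata recovered in the group means
  g3 <- factor(rep(c("open", "tfbs_pwm", "tfbs_chip"), each = 150),
               levels = c("open", "tfbs_pwm", "tfbs_chip"))
  v3 <- pmin(1, pmax(0, rnorm(450, 0.2 + 0.1 * (as.integer(g3) - 1), 0.05)))
  r3 <- compare_discordance_by_group(v3, g3)
  expect_true(all(diff(r3$means) > 0))
  expect_error(compare_discordance_by_group(base, rep("x", 200)), ">= 2")
})
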