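test_that("window placements tile the full receptive field without gaps", {
  # full-scale geometry: offsets 0 and +/- 40,960 bp
  dcfg <- data_config()
  v <- data.frame(id = "v1", chrom = "chr1", pos = 1000000)
  pl <- window_placements(v, dcfg)
  expect_setequal(pl$window_start - pl$window_start[pl$placement == "centre"],
                  c(-40960, 0, 40960))
  # toy geometry: offsets +/- 1,024 bp
  tcfg <- toy_data_config()
  plt <- window_placements(data.frame(id = "v", chrom = "chr1",
                                      pos = 20000), tcfg)
  expect_setequal(plt$window_start -
                    plt$window_start[plt$placement == "centre"],
                  c(-1024, 0, 1024))
  # kept segments are disjoint, contiguous and cover exactly input_len
  segs <- lapply(seq_len(nrow(plt)), function(i) {
    ws <- plt$window_start[i]
    b <- (plt$keep_from[i]:plt$keep_to[i]) - 1
    ws + c(b * tcfg$bin, (b + 1) * tcfg$bin - 1)
  })
  covered <- sort(unlist(lapply(seq_len(nrow(plt)), function(i) {
    ws <- plt$window_start[i]
    unlist(lapply((plt$keep_from[i]:plt$keep_to[i]) - 1, function(b)
      (ws + b * tcfg$bin):(ws + (b + 1) * tcfg$bin - 1)))
  })))
  expect_equal(length(covered), tcfg$input_len)
  expect_true(all(diff(covered) == 1))              # contiguous, no overlap

  # placements off the chromosome are clipped with a warning
  g <- genome_index("chr1", 16384)
  expect_warning(short <- window_placements(
    data.frame(id = "v", chrom = "chr1", pos = 1500), tcfg, g), "clipped")
  expect_lt(nrow(short), 3)
})

test_that("score is exactly zero when alt equals ref and uses 24 passes", {
  fx <- study_fixture()
  model <- study_model()
  v <- data.frame(id = "same", chrom = "chr1", pos = 30000,
                  ref = substring(fx$sim$sequences$chr1, 30001, 30001))
  v$alt <- v$ref
  s <- score_variant(model, fx$ds, v, fx$ds$cells[1])
  expect_equal(unname(s$score), rep(0, 3))
  expect_identical(s$n_passes, 24L)
})

test_that("ref-allele mismatches are rejected", {
  fx <- study_fixture()
  model <- study_model()
  actual <- substring(fx$sim$sequences$chr1, 30001, 30001)
  wrong <- setdiff(c("A", "C", "G", "T"), actual)[1]
  v <- data.frame(id = "bad", chrom = "chr1", pos = 30000, ref = wrong,
                  alt = actual)
  expect_error(score_variant(model, fx$ds, v, fx$ds$cells[1]), "mismatch")
})

test_that("a linear model recovers the analytic weight-difference score", {
  fx <- study_fixture()
  cfg <- fx$dcfg
  # prediction = column-sum of one-hot weighted by per-base weights, folded
  # per bin: scoring must then equal the summed weight difference between
  # alleles over every placement that covers the variant
  set.seed(33)
  wbase <- matrix(rnorm(4), 1, 4)
  nb <- n_bins(cfg)
  lin_predict <- function(oh, feats) {
    per_base <- as.numeric(oh %*% t(wbase))
    centre <- per_base[(crop_margin(cfg) + 1):(crop_margin(cfg) +
                                                 cfg$window_len)]
    m <- matrix(centre, ncol = 1)
    grp <- rep(seq_len(nb), each = cfg$bin)
    matrix(rep(rowsum(m, grp), 3), nb, 3)
  }
  v <- data.frame(id = "lin", chrom = "chr1", pos = 30000,
                  ref = substring(fx$sim$sequences$chr1, 30001, 30001))
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  s <- score_variant(NULL, fx$ds, v, fx$ds$cells[1], augment = FALSE,
                     predict_fn = lin_predict)
  base_w <- stats::setNames(as.numeric(wbase), c("A", "C", "G", "T"))
  # the variant lies in the kept segment of exactly one placement per
  # augmentation, so each augmentation contributes the weight difference once
  expected <- base_w[[v$alt]] - base_w[[v$ref]]
  expect_equal(unname(s$score), rep(expected, 3), tolerance = 1e-9)
})

test_that("allele swap flips the score sign exactly", {
  fx <- study_fixture()
  model <- study_model()
  v <- data.frame(id = "swapme", chrom = "chr1", pos = 30000,
                  ref = substring(fx$sim$sequences$chr1, 30001, 30001))
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  s_fwd <- score_variant(model, fx$ds, v, fx$ds$cells[1])
  # place the alt allele on the genome and swap the alleles
  ds2 <- fx$ds
  substring(ds2$sequences$chr1, 30001, 30001) <- v$alt
  v2 <- data.frame(id = "swapme", chrom = "chr1", pos = 30000,
                   ref = v$alt, alt = v$ref)
  s_rev <- score_variant(model, ds2, v2, fx$ds$cells[1])
  expect_equal(s_rev$score, -s_fwd$score, tolerance = 1e-9)
})

test_that("hQTL munging drops trans, far and off-whitelist records", {
  rec <- function(id, chrom, pos, pchrom, pstart, pend) {
    data.frame(id = id, chrom = chrom, pos = pos, peak_chrom = pchrom,
               peak_start = pstart, peak_end = pend, beta = 0.5, p = 0.01)
  }
  records <- rbind(
    rec("s1", "chr1", 100, "chr2", 50, 150),              # trans
    rec("s2", "chr1", 100, "chr1", 5100, 5200),           # far (> 1000)
    rec("s3", "chr1", 100, "chr1", 1100, 1200),           # boundary: kept
    rec("s4", "chr1", 100, "chr1", 90, 200))              # inside peak
  out <- munge_hqtl(records, receptive_field = 1000)
  expect_setequal(out$id, c("s3", "s4"))
  out_wl <- munge_hqtl(records, 1000, whitelist = "s4")
  expect_identical(out_wl$id, "s4")

  # 10-record toy set: 3 trans, 2 far, 1 off-whitelist, disjoint -> 4 left
  ten <- rbind(rec("t1", "chr1", 0, "chr2", 0, 10),
               rec("t2", "chr1", 0, "chr2", 0, 10),
               rec("t3", "chr1", 0, "chr2", 0, 10),
               rec("t4", "chr1", 0, "chr1", 9000, 9100),
               rec("t5", "chr1", 0, "chr1", 9000, 9100),
               rec("t6", "chr1", 0, "chr1", 10, 20),
               rec("t7", "chr1", 0, "chr1", 10, 20),
               rec("t8", "chr1", 0, "chr1", 10, 20),
               rec("t9", "chr1", 0, "chr1", 10, 20),
               rec("t10", "chr1", 0, "chr1", 10, 20))
  out10 <- munge_hqtl(ten, 1000, whitelist = paste0("t", c(1:5, 7:10)))
  expect_equal(nrow(out10), 4)

  bad <- rbind(rec("b1", "chr1", 0, "chr1", 10, 20),
               rec("b2", "chr1", 0, "chr1", 10, 20))
  bad$beta[2] <- NA
  out_bad <- munge_hqtl(bad, 1000)
  expect_equal(attr(out_bad, "n_skipped"), 1)
})

test_that("marginal aggregation is |G|^(-1/2) times the beta sum", {
  one <- data.frame(id = "s", beta = 0.3)
  expect_equal(aggregate_marginal(one)$alpha, 0.3)
  four <- data.frame(id = rep("s", 4), beta = rep(1, 4))
  expect_equal(aggregate_marginal(four)$alpha, 2)
  # brute-force oracle over 1000 random SNP groups
  set.seed(51)
  for (i in 1:1000) {
    n <- sample(1:6, 1)
    df <- data.frame(id = "x", beta = rnorm(n))
    loop_sum <- 0
    for (k in seq_len(n)) loop_sum <- loop_sum + df$beta[k]
    expect_equal(aggregate_marginal(df)$alpha, loop_sum / sqrt(n),
                 tolerance = 1e-12)
  }
})

test_that("concordance report behaves at the identities and under the null", {
  marg <- data.frame(id = paste0("s", 1:40), alpha = rnorm(40))
  same <- data.frame(id = marg$id, score = marg$alpha)
  rep1 <- export_and_concord(same, marg)
  expect_equal(rep1$concordance, 1)
  expect_equal(rep1$rank_cor, 1)
  flip <- data.frame(id = marg$id, score = -marg$alpha)
  expect_equal(export_and_concord(flip, marg)$concordance, 0)

  # a null with exactly 50/50 sign agreement at n = 1000 is never
  # significant, whichever permutation realises it (3 seeds)
  for (s in 1:3) {
    set.seed(s)
    m <- data.frame(id = paste0("r", 1:1000),
                    alpha = sample(c(-1, 1), 1000, replace = TRUE))
    agree <- sample(rep(c(1, -1), each = 500))
    sc <- data.frame(id = m$id, score = m$alpha * agree)
    expect_gt(export_and_concord(sc, m)$binom_p, 0.05)
  }

  expect_error(export_and_concord(data.frame(id = "a", score = 1),
                                  data.frame(id = "b", alpha = 1)),
               "empty join")
})

test_that("sumstats export is a joinable tab-separated file", {
  marg <- data.frame(id = c("s1", "s2"), alpha = c(1, -1))
  sc <- data.frame(id = c("s1", "s2"), score = c(0.5, -0.2))
  vars <- data.frame(id = c("s1", "s2"), chrom = "chr1", pos = c(1, 2),
                     ref = c("A", "C"), alt = c("G", "T"))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_and_concord(sc, marg, variants = vars, path = path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_identical(names(tab), c("SNP", "A1", "A2", "Z"))
  expect_equal(tab$Z, c(0.5, -0.2))
})
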