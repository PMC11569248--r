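test_that("enumerate_candidates tiles, respects flanks and the blacklist", {
  cfg <- tiny_data_cfg()
  margin <- max(crop_margin(cfg), (cfg$local_atac_len - cfg$window_len) / 2) +
    cfg$shift_max
  # 10 windows tile the chromosome; ends lacking flank margin are dropped
  g <- genome_index("chr1", 10 * cfg$window_len)
  cand <- enumerate_candidates(g, interval_set(), cfg)
  lost_per_side <- ceiling(margin / cfg$window_len)
  expect_equal(nrow(cand), 10 - 2 * lost_per_side)
  expect_equal(cand$input_start, cand$window_start - crop_margin(cfg))

  # blacklist covering everything removes every window
  bl_all <- interval_set("chr1", 0, 10 * cfg$window_len)
  expect_warning(none <- enumerate_candidates(g, bl_all, cfg), "no candidate")
  expect_equal(nrow(none), 0)

  # a blacklist interval inside exactly one window removes just that one
  hit <- cand$window_start[2] + 10
  bl_one <- interval_set("chr1", hit, hit + 50)
  cand2 <- enumerate_candidates(g, bl_one, cfg)
  expect_equal(nrow(cand2), nrow(cand) - 1)
  expect_false(cand$window_start[2] %in% cand2$window_start)
})

test_that("coverage filter applies the strict > 12.5% rule at the peak cutoff", {
  # full-scale window: 896 bins of 128 bp
  cfg <- data_config(val_chroms = character())
  nb <- n_bins(cfg)
  g <- genome_index("chr1", cfg$window_len)
  region <- data.frame(chrom = "chr1", window_start = 0,
                       input_start = -crop_margin(cfg),
                       admitting_mark = "dna-only")
  mk_track <- function(n_peak) {
    v <- rep(0, nb); v[seq_len(n_peak)] <- 2     # exactly at the cutoff
    binned_track(g, 128, list(chr1 = v), assay = "m", cell = "c")
  }
  res113 <- coverage_filter(region, list(m = list(mk_track(113))), cfg)
  expect_equal(nrow(res113$m), 1)               # 113/896 = 0.1261 > 0.125
  res112 <- coverage_filter(region, list(m = list(mk_track(112))), cfg)
  expect_equal(nrow(res112$m), 0)               # 112/896 = 0.125 exactly

  expect_equal(nrow(coverage_filter(region,
                                    list(m = list(mk_track(0))), cfg)$m), 0)
  all_peak <- mk_track(nb)
  expect_equal(nrow(coverage_filter(region,
                                    list(m = list(all_peak)), cfg)$m), 1)
})

test_that("balance_marks equalises per-mark counts reproducibly", {
  cfg <- tiny_data_cfg()
  mk <- function(n) region_spec("chr1", seq_len(n) * cfg$window_len, cfg)
  pm <- list(a = mk(5), b = mk(3), c = mk(4))
  bal <- balance_marks(pm, seed = 11)
  expect_equal(nrow(bal), 9)
  expect_equal(as.integer(table(bal$admitting_mark)[c("a", "b", "c")]),
               c(3L, 3L, 3L))
  expect_identical(balance_marks(pm, seed = 11), bal)

  pm2 <- list(a = mk(100), b = mk(10))
  for (s in 1:10) {
    counts <- table(balance_marks(pm2, seed = s)$admitting_mark)
    expect_equal(as.integer(counts[c("a", "b")]), c(10L, 10L))
  }
})

test_that("build_distribution reproduces the worked 104-cell example", {
  vals <- c(rep(0, 102), rep(5.5, 2))
  d <- build_distribution(vals)
  expect_equal(round(d[1], 2), 0.98)
  expect_equal(round(d[length(d)], 3), 0.019)
  expect_equal(sum(d), 1)

  all_zero <- build_distribution(rep(0, 104))
  expect_equal(all_zero, c(1, rep(0, 9)))

  hand <- build_distribution(c(0.1, 0.6, 1.1, 9.9))
  expect_equal(hand[c(1, 2, 3, 10)], rep(0.25, 4))

  expect_error(build_distribution(c(-1, 2)), "negative")
})

test_that("build_distribution equals a brute-force histogram on random draws", {
  edges <- seq(0.5, 4.5, by = 0.5)
  set.seed(99)
  for (rep in 1:1000) {
    v <- stats::rexp(sample(3:30, 1))
    got <- build_distribution(v, edges)
    breaks <- c(0, edges, Inf)
    oracle <- vapply(seq_len(length(breaks) - 1), function(k)
      mean(v >= breaks[k] & v < breaks[k + 1]), numeric(1))
    expect_equal(got, oracle)
  }
})

test_that("build_targets matches a loop-based oracle on a 3-cell fixture", {
  cfg <- tiny_data_cfg()
  gs <- random_genome(len = 2048)
  nbv <- 2048 / cfg$bin
  set.seed(5)
  cells <- c("c1", "c2", "c3")
  tab <- lapply(cells, function(cl) {
    list(m1 = random_track(gs$genome, bin = cfg$bin,
                           seed = match(cl, cells), assay = "m1", cell = cl))
  })
  names(tab) <- cells
  region <- data.frame(chrom = "chr1", window_start = 256)
  tb <- build_targets(region, tab, "c2", cfg)
  nb <- n_bins(cfg)
  b0 <- 256 / cfg$bin
  for (b in seq_len(nb)) {
    raw <- vapply(cells, function(cl)
      tab[[cl]]$m1$values$chr1[b0 + b], numeric(1))
    expect_equal(unname(tb$avg[b, 1]), mean(asinh(raw)))
    expect_equal(tb$dist[b, 1, ], build_distribution(raw, cfg$dist_edges))
    expect_equal(unname(tb$delta[b, 1]),
                 asinh(raw[["c2"]]) - mean(asinh(raw)))
  }
  # simplex and reconstruction invariants
  expect_equal(apply(tb$dist, c(1, 2), sum), matrix(1, nb, 1),
               ignore_attr = TRUE)
  expect_equal(tb$cell_signal, tb$avg + tb$delta, tolerance = 1e-6)

  # a cell equal to the average has an all-zero delta
  same <- list(x = tab$c1, y = tab$c1)
  tb2 <- build_targets(region, same, "x", cfg)
  expect_equal(max(abs(tb2$delta)), 0)

  expect_error(build_targets(region, tab, "nope", cfg), "absent")
})

test_that("splits hold out cells and chromosomes with seeded augmentation", {
  cfg <- tiny_data_cfg(seed = 21)
  regions <- rbind(region_spec("chr1", (2:5) * 1024, cfg),
                   region_spec("chr2", (2:4) * 1024, cfg))
  cells <- sprintf("c%02d", 1:10)
  sp <- make_splits_and_augment(regions, cells, cfg)
  expect_length(sp$val_cells, 2)                  # 20% of 10
  expect_true(all(!sp$train$cell %in% sp$val_cells))
  expect_true(all(sp$val$cell %in% sp$val_cells))
  expect_true(all(sp$train$chrom != "chr2"))
  expect_true(all(sp$val$chrom == "chr2"))
  expect_equal(nrow(sp$train) %% 2, 0)            # both strands per item
  expect_setequal(unique(sp$train$strand), c("-", "+"))
  expect_true(all(abs(sp$train$shift) <= cfg$shift_max))
  expect_true(all(sp$train$shift %% cfg$bin == 0))

  sp2 <- make_splits_and_augment(regions, cells, cfg)
  expect_identical(sp2$val$window_start, sp$val$window_start)

  cfg2 <- tiny_data_cfg(val_cell_frac = 0.04)
  expect_error(make_splits_and_augment(regions, cells, cfg2), "zero")
})
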