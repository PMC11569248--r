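test_that("genome simulation is seed-deterministic and plants real motif instances", {
  scfg <- sim_config(seed = 5)
  sim1 <- simulate_genome(scfg)
  sim2 <- simulate_genome(scfg)
  expect_identical(sim1$sequences, sim2$sequences)
  expect_identical(sim1$occurrences, sim2$occurrences)

  g <- sim1$grammar
  occ <- sim1$occurrences[sim1$occurrences$intact, ]
  for (i in seq_len(nrow(occ))) {
    mot <- g$motifs[occ$motif[i]]
    written <- if (occ$strand[i] == "+") mot else chromcast:::revcomp_chr(mot)
    found <- substring(sim1$sequences[[occ$chrom[i]]],
                       occ$motif_start[i] + 1,
                       occ$motif_start[i] + nchar(mot))
    expect_identical(found, written)
  }
})

test_that("planted site counts follow the configured Poisson intensity", {
  counts <- numeric(10)
  lambda <- NA
  for (s in 1:10) {
    scfg <- sim_config(seed = 100 + s)
    sim <- simulate_genome(scfg)
    counts[s] <- nrow(sim$occurrences)
    lambda <- scfg$n_chrom * scfg$sites_per_kb * scfg$chrom_len / 1000
  }
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 10))
})

test_that("track simulation realises the planted grammar", {
  # all-ones usage: cells identical up to noise
  scfg <- sim_config(seed = 7, n_cells = 3, noise_sd = 0)
  sim <- simulate_genome(scfg)
  sim$grammar$usage[] <- 1
  tr <- simulate_tracks(sim, scfg)
  expect_equal(tr$marks$cell01$mark1$values, tr$marks$cell02$mark1$values)

  # zero noise, single cell: peak maximum equals the amplitude product
  scfg1 <- sim_config(seed = 8, n_cells = 1, n_shared_motifs = 1,
                      noise_sd = 0)
  sim1 <- simulate_genome(scfg1)
  tr1 <- simulate_tracks(sim1, scfg1)
  g <- sim1$grammar
  occ <- sim1$occurrences[sim1$occurrences$intact, ]
  # pick a site isolated from every other site (no bump overlap)
  iso <- NULL
  for (i in seq_len(nrow(occ))) {
    d <- abs(occ$centre - occ$centre[i])
    if (sum(d < 6 * g$peak_halfwidth &
              occ$chrom == occ$chrom[i]) == 1) { iso <- occ[i, ]; break }
  }
  expect_false(is.null(iso))
  amp <- unname(g$peak_amp * g$usage[1, iso$motif] *
                  g$affinity[iso$motif, 1])
  v <- tr1$marks$cell01$mark1$values[[iso$chrom]]
  bin_i <- floor(iso$centre / scfg1$sim_bin) + 1
  expect_equal(v[bin_i], amp, tolerance = 1e-9)

  # cells with disjoint private motifs disagree at private sites
  scfg2 <- sim_config(seed = 9, noise_sd = 0)
  sim2 <- simulate_genome(scfg2)
  tr2 <- simulate_tracks(sim2, scfg2)
  g2 <- sim2$grammar
  priv <- sim2$occurrences[sim2$occurrences$intact &
                             sim2$occurrences$motif == g2$n_shared + 1, ][1, ]
  b <- floor(priv$centre / scfg2$sim_bin) + 1
  own <- tr2$marks$cell01$mark1$values[[priv$chrom]][b]
  other <- tr2$marks$cell02$mark1$values[[priv$chrom]][b]
  expect_gt(own, 2)          # a peak for the owning cell
  expect_lt(other, own / 2)  # absent (up to bump overlap) for others
})

test_that("marker genes separate cells beyond a usage-shuffled null", {
  hits <- 0
  for (s in 1:10) {
    scfg <- sim_config(seed = 200 + s)
    sim <- simulate_genome(scfg)
    tracks <- simulate_tracks(sim, scfg)
    dcfg <- toy_data_config(seed = s)
    mg <- simulate_marker_genes(sim, tracks, scfg, dcfg)
    expect_equal(nrow(mg), scfg$n_marker_genes)
    if (attr(mg, "separation") > 1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("hQTL simulation plants signed effects and the configured decoys", {
  fx <- study_fixture()
  hq <- simulate_hqtl(fx$sim, fx$scfg)
  expect_equal(sum(hq$truth$type == "trans"), fx$scfg$n_trans_decoys)
  expect_equal(sum(hq$truth$type == "far"), fx$scfg$n_far_decoys)
  expect_true(all(hq$truth$true_effect[hq$truth$type != "causal"] == 0))
  expect_true(all(hq$records$p > 0 & hq$records$p <= 1))
  # every variant's ref allele matches the genome
  for (i in seq_len(nrow(hq$variants)))
    expect_silent(chromcast:::validate_variant(fx$ds, hq$variants[i, ]))

  # in the noise -> 0 limit betas carry the planted sign everywhere
  scfg0 <- sim_config(seed = 3, hqtl_noise_sd = 1e-12)
  sim0 <- simulate_genome(scfg0)
  hq0 <- simulate_hqtl(sim0, scfg0)
  causal <- merge(hq0$records, hq0$truth[hq0$truth$type == "causal", ],
                  by = "id")
  expect_true(all(sign(causal$beta) == sign(causal$true_effect)))
})

test_that("generated artifacts round-trip through the track reader", {
  scfg <- sim_config(seed = 12, n_cells = 2, n_marks = 1,
                     n_marker_genes = 2)
  dir <- withr::local_tempdir()
  sim <- simulate_genome(scfg, dir = dir)
  tr <- simulate_tracks(sim, scfg, dir = dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(length(fa), scfg$n_chrom)
  bl <- read_bed(file.path(dir, "blacklist.bed"), genome = sim$genome)
  expect_equal(nrow(bl), scfg$blacklist_n * scfg$n_chrom)
  back <- track_io(file.path(dir, "cell01_mark1.bedGraph"), "read",
                   "bedGraph", sim$genome, bin_size = scfg$sim_bin)
  expect_identical(back$values, tr$marks$cell01$mark1$values)
})

test_that("the default study conditions yield a balanced training set quickly", {
  t0 <- Sys.time()
  fx <- study_fixture()
  expect_gte(nrow(fx$ds$regions), 50)
  counts <- table(fx$ds$regions$admitting_mark)
  expect_true(all(counts == counts[1]))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 60)
})
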