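#' Planted regulatory grammar
#'
#' The generative model behind every synthetic fixture: a set of consensus
#' motifs, a per-motif mark-affinity vector, and a cells-by-motifs usage
#' matrix. Shared motifs (usage 1 everywhere) produce peaks common to all
#' cells; each cell additionally owns one private motif, guaranteeing at
#' least one planted cell-specific peak region per cell. Accessibility tracks
#' are a monotone function of total site activity, so the accessibility delta
#' carries the cell-specific signal the model is meant to exploit.
#'
#' @param cfg A `SimConfig`.
#' @param seed Seed (defaults to `cfg$seed`).
#' @return A list of class `RegulatoryGrammar` with `motifs`, `affinity`
#'   (motifs x marks), `usage` (cells x motifs), `peak_halfwidth`,
#'   `peak_amp`, `atac_amp`, `noise_sd`, `cells`, `marks`.
#' @export
regulatory_grammar <- function(cfg, seed = cfg$seed) {
  nn_seeded(seed, {
    n_motifs <- cfg$n_shared_motifs + cfg$n_cells
    motifs <- vapply(seq_len(n_motifs), function(i)
      paste(sample(c("A", "C", "G", "T"), cfg$motif_len, replace = TRUE),
            collapse = ""), character(1))
    # regenerate any duplicated or self-reverse-complementary consensus
    while (anyDuplicated(motifs)) {
      i <- anyDuplicated(motifs)
      motifs[i] <- paste(sample(c("A", "C", "G", "T"), cfg$motif_len,
                                replace = TRUE), collapse = "")
    }
    affinity <- matrix(stats::runif(n_motifs * cfg$n_marks, 0.4, 1),
                       n_motifs, cfg$n_marks)
    usage <- matrix(0, cfg$n_cells, n_motifs)
    usage[, seq_len(cfg$n_shared_motifs)] <- 1
    for (c in seq_len(cfg$n_cells))
      usage[c, cfg$n_shared_motifs + c] <- 1
    cells <- sprintf("cell%02d", seq_len(cfg$n_cells))
    marks <- sprintf("mark%d", seq_len(cfg$n_marks))
    dimnames(usage) <- list(cells, NULL)
    dimnames(affinity) <- list(NULL, marks)
    structure(list(motifs = motifs, affinity = affinity, usage = usage,
                   peak_halfwidth = cfg$peak_halfwidth,
                   peak_amp = cfg$peak_amp, atac_amp = cfg$atac_amp,
                   noise_sd = cfg$noise_sd, cells = cells, marks = marks,
                   n_shared = cfg$n_shared_motifs),
              class = "RegulatoryGrammar")
  })
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

#' Simulate a genome with planted motif sites
#'
#' Uniform-random background sequence with motif instances planted at
#' Poisson-distributed counts on a coarse grid (so sites never overlap), a
#' small planted blacklist, and an occurrence table recording site, motif,
#' strand and whether the instance is intact or carries a single-base lesion
#' (used to plant restorable hQTL variants). Site centres snap to
#' `sim_bin`-bin centres so planted peak maxima are exact.
#'
#' @param cfg A `SimConfig`.
#' @param grammar A `RegulatoryGrammar` (built from `cfg` when `NULL`).
#' @param dir Optional output directory; writes `genome.fa`,
#'   `blacklist.bed` and `occurrences.tsv`.
#' @return List of class `cc_sim_genome` with `genome` (GenomeIndex),
#'   `sequences` (named character), `blacklist` (IntervalSet),
#'   `occurrences` (data frame) and `grammar`.
#' @export
simulate_genome <- function(cfg, grammar = NULL, dir = NULL) {
  if (is.null(grammar)) grammar <- regulatory_grammar(cfg)
  if (nchar(grammar$motifs[1]) > cfg$chrom_len)
    stop("chromcast_error: motif longer than chromosome")
  nn_seeded(cfg$seed + 1000L, {
    chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
    genome <- genome_index(chroms, rep(cfg$chrom_len, cfg$n_chrom))
    n_motifs <- length(grammar$motifs)
    grid_step <- 512L
    margin <- 4096L
    occ <- list()
    sequences <- list()
    for (chrom in chroms) {
      len <- cfg$chrom_len
      seqv <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      slots <- seq(margin, len - margin - grid_step, by = grid_step)
      n_sites <- min(stats::rpois(1, cfg$sites_per_kb * len / 1000),
                     length(slots))
      pos_slot <- sample(slots, n_sites)
      # every motif appears at least twice per chromosome (if room allows)
      forced <- rep(seq_len(n_motifs), 2)
      motif_id <- c(sample(forced),
                    sample.int(n_motifs, max(0, n_sites - length(forced)),
                               replace = TRUE))[seq_len(n_sites)]
      strand <- sample(c("+", "-"), n_sites, replace = TRUE)
      intact <- stats::runif(n_sites) > 0.25
      centre <- numeric(n_sites); mstart <- integer(n_sites)
      lesion_off <- rep(NA_integer_, n_sites)
      lesion_ref <- rep(NA_character_, n_sites)
      for (i in seq_len(n_sites)) {
        mot <- grammar$motifs[motif_id[i]]
        mlen <- nchar(mot)
        # snap the site centre to a sim-bin centre
        b <- floor((pos_slot[i] + grid_step / 2) / cfg$sim_bin)
        p <- (b + 0.5) * cfg$sim_bin
        s0 <- as.integer(floor(p - mlen / 2))         # 0-based motif start
        written <- if (strand[i] == "+") mot else revcomp_chr(mot)
        wchars <- strsplit(written, "")[[1]]
        if (!intact[i]) {
          off <- sample.int(mlen, 1)
          orig <- wchars[off]
          wchars[off] <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
          lesion_off[i] <- off
          lesion_ref[i] <- orig
        }
        seqv[(s0 + 1):(s0 + mlen)] <- wchars
        centre[i] <- p
        mstart[i] <- s0
      }
      sequences[[chrom]] <- paste(seqv, collapse = "")
      occ[[chrom]] <- data.frame(
        chrom = chrom, centre = centre, motif_start = mstart,
        motif = motif_id, strand = strand, intact = intact,
        lesion_offset = lesion_off, lesion_consensus_base = lesion_ref,
        stringsAsFactors = FALSE)
    }
    occurrences <- do.call(rbind, c(occ, list(make.row.names = FALSE)))
    bl <- list()
    for (chrom in chroms) {
      st <- sort(sample(seq(margin, cfg$chrom_len - margin, by = 1),
                        cfg$blacklist_n))
      bl[[chrom]] <- data.frame(chrom = chrom, start = st,
                                end = st + cfg$blacklist_len)
    }
    bldf <- do.call(rbind, bl)
    blacklist <- interval_set(bldf$chrom, bldf$start, bldf$end,
                              genome = genome)
    out <- structure(list(genome = genome, sequences = sequences,
                          blacklist = blacklist, occurrences = occurrences,
                          grammar = grammar),
                     class = "cc_sim_genome")
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      ss <- Biostrings::DNAStringSet(unlist(sequences))
      Biostrings::writeXStringSet(ss, file.path(dir, "genome.fa"))
      write_bed(blacklist, file.path(dir, "blacklist.bed"))
      utils::write.table(occurrences, file.path(dir, "occurrences.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })
}

gaussian_bump <- function(n_bins_chrom, bin, centre, amp, sigma) {
  lo <- max(0, floor((centre - 3 * sigma) / bin))
  hi <- min(n_bins_chrom - 1, ceiling((centre + 3 * sigma) / bin))
  if (hi < lo) return(NULL)
  bins <- lo:hi
  mid <- (bins + 0.5) * bin
  list(idx = bins + 1, val = amp * exp(-(mid - centre)^2 / (2 * sigma^2)))
}

#' Simulate multi-cell histone-mark and accessibility tracks
#'
#' Each intact motif site contributes, in cell c and mark m, a truncated
#' Gaussian peak of amplitude `peak_amp * usage[c, motif] * affinity[motif,
#' m]` on the -log10 p-value scale; accessibility gets amplitude `atac_amp *
#' usage[c, motif]` regardless of mark, plus non-negative half-normal noise.
#'
#' @param sim A `cc_sim_genome` from [simulate_genome()].
#' @param cfg The `SimConfig` used to build it.
#' @param dir Optional output directory for bedGraph files.
#' @return List with `marks` (`tracks[[cell]][[mark]]`) and `atac`
#'   (`atac[[cell]]`), all neglog10p-scale `BinnedTrack`s at `cfg$sim_bin`.
#' @export
simulate_tracks <- function(sim, cfg, dir = NULL) {
  g <- sim$grammar
  nn_seeded(cfg$seed + 2000L, {
    nb <- as.integer(ceiling(cfg$chrom_len / cfg$sim_bin))
    occ <- sim$occurrences[sim$occurrences$intact, , drop = FALSE]
    marks_out <- list()
    atac_out <- list()
    for (ci in seq_along(g$cells)) {
      cell <- g$cells[ci]
      cell_tracks <- list()
      atac_vals <- list()
      mark_vals <- lapply(g$marks, function(m) list())
      names(mark_vals) <- g$marks
      for (chrom in sim$genome$names) {
        oc <- occ[occ$chrom == chrom, , drop = FALSE]
        base_m <- lapply(g$marks, function(m) numeric(nb))
        names(base_m) <- g$marks
        base_a <- numeric(nb)
        for (i in seq_len(nrow(oc))) {
          u <- g$usage[ci, oc$motif[i]]
          if (u == 0) next
          for (mi in seq_along(g$marks)) {
            amp <- g$peak_amp * u * g$affinity[oc$motif[i], mi]
            bp <- gaussian_bump(nb, cfg$sim_bin, oc$centre[i], amp,
                                g$peak_halfwidth)
            if (!is.null(bp))
              base_m[[mi]][bp$idx] <- base_m[[mi]][bp$idx] + bp$val
          }
          bpa <- gaussian_bump(nb, cfg$sim_bin, oc$centre[i],
                               g$atac_amp * u, g$peak_halfwidth)
          if (!is.null(bpa)) base_a[bpa$idx] <- base_a[bpa$idx] + bpa$val
        }
        for (mi in seq_along(g$marks))
          mark_vals[[mi]][[chrom]] <- base_m[[mi]] +
            abs(stats::rnorm(nb, 0, g$noise_sd))
        atac_vals[[chrom]] <- base_a + abs(stats::rnorm(nb, 0, g$noise_sd))
      }
      for (mi in seq_along(g$marks))
        cell_tracks[[g$marks[mi]]] <- binned_track(
          sim$genome, cfg$sim_bin, mark_vals[[mi]], assay = g$marks[mi],
          cell = cell, scale = "neglog10p")
      marks_out[[cell]] <- cell_tracks
      atac_out[[cell]] <- binned_track(sim$genome, cfg$sim_bin, atac_vals,
                                       assay = "ATAC", cell = cell,
                                       scale = "neglog10p")
    }
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (cell in g$cells) {
        for (m in g$marks)
          track_io(file.path(dir, paste0(cell, "_", m, ".bedGraph")),
                   "write", "bedGraph", sim$genome,
                   track = marks_out[[cell]][[m]])
        track_io(file.path(dir, paste0(cell, "_ATAC.bedGraph")),
                 "write", "bedGraph", sim$genome, track = atac_out[[cell]])
      }
    }
    list(marks = marks_out, atac = atac_out)
  })
}

#' Place marker-gene TSSs at cell-discriminative sites
#'
#' Marker TSSs sit on private (cell-specific) motif sites, cycling through
#' cells, so that accessibility around them separates cell types. The
#' returned table carries a separation statistic comparing mean
#' between-cell distance of the global accessibility vectors against a
#' usage-shuffled construction.
#'
#' @param sim A `cc_sim_genome`.
#' @param tracks Output of [simulate_tracks()].
#' @param cfg The `SimConfig`.
#' @param dcfg A `DataConfig` supplying `tss_window` and `global_bin`.
#' @param path Optional TSV output path.
#' @return Data frame (gene, chrom, tss) with attribute `separation`.
#' @export
simulate_marker_genes <- function(sim, tracks, cfg, dcfg = toy_data_config(),
                                  path = NULL) {
  g <- sim$grammar
  occ <- sim$occurrences[sim$occurrences$intact, , drop = FALSE]
  private <- occ[occ$motif > g$n_shared, , drop = FALSE]
  if (nrow(private) < 1)
    stop("chromcast_error: no private sites to anchor marker genes")
  private$owner <- private$motif - g$n_shared
  nn_seeded(cfg$seed + 3000L, {
    rows <- list()
    owners <- rep(seq_len(cfg$n_cells), length.out = cfg$n_marker_genes)
    used <- integer(0)
    for (i in seq_len(cfg$n_marker_genes)) {
      cand <- setdiff(which(private$owner == owners[i]), used)
      if (length(cand) == 0) cand <- setdiff(seq_len(nrow(private)), used)
      if (length(cand) == 0)
        stop("chromcast_error: cannot place requested marker-gene count")
      j <- cand[sample.int(length(cand), 1)]
      used <- c(used, j)
      rows[[i]] <- data.frame(gene = sprintf("marker%03d", i),
                              chrom = private$chrom[j],
                              tss = round(private$centre[j]))
    }
    mg <- do.call(rbind, rows)
    gv <- vapply(g$cells, function(cell)
      global_features(tracks$atac[[cell]], mg, dcfg), numeric(
        cfg$n_marker_genes * (dcfg$tss_window %/% dcfg$global_bin)))
    d_obs <- mean(stats::dist(t(gv)))
    perm <- sample(ncol(gv))
    # distance under shuffled cell-to-usage assignment of private anchors:
    # average distance between each cell's vector and a random other cell's
    d_null <- mean(abs(gv - gv[, perm]))
    attr(mg, "separation") <- d_obs / max(d_null, 1e-12)
    if (!is.null(path))
      utils::write.table(mg, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    mg
  })
}

#' Global accessibility feature vector for one cell
#'
#' Accessibility (arcsinh of -log10 p) in `tss_window` bp around each marker
#' TSS, averaged at `global_bin` resolution and concatenated over genes. The
#' vector is a property of the cell only, identical for every genomic window.
#'
#' @param atac_track The cell's ATAC `BinnedTrack` (neglog10p scale).
#' @param marker_genes Data frame with columns `chrom`, `tss`.
#' @param dcfg A `DataConfig`.
#' @return Numeric vector of length `n_genes * tss_window / global_bin`.
#' @export
global_features <- function(atac_track, marker_genes, dcfg) {
  per_gene <- dcfg$tss_window %/% dcfg$global_bin
  half <- dcfg$tss_window / 2
  out <- numeric(0)
  for (i in seq_len(nrow(marker_genes))) {
    v <- window_any_bin(atac_track, marker_genes$chrom[i],
                        marker_genes$tss[i] - half, dcfg$tss_window,
                        dcfg$global_bin)
    out <- c(out, v)
  }
  asinh(out)
}

# Average an arbitrary (not necessarily bin-aligned) window of a track at a
# chosen output resolution, clipping at chromosome ends (zero-filled).
window_any_bin <- function(track, chrom, start, width, out_bin) {
  len <- chrom_length(track$genome, chrom)
  v <- track$values[[chrom]]
  per_base <- numeric(width)
  lo <- max(0, start); hi <- min(len, start + width)
  if (hi > lo) {
    idx <- (floor(lo):(hi - 1)) %/% track$bin_size + 1
    per_base[(lo - start + 1):(hi - start)] <- v[idx]
  }
  n_out <- width %/% out_bin
  rowsum(per_base[seq_len(n_out * out_bin)],
         rep(seq_len(n_out), each = out_bin))[, 1] / out_bin
}

#' Simulate hQTL variants with known signed effects
#'
#' Plants variants inside motif instances: at intact sites the alternative
#' allele breaks the consensus (negative effect on overlapping peak
#' amplitude), at lesioned sites it restores it (positive effect). The true
#' effect on a peak equals the study-cell amplitude with the motif intact
#' minus the amplitude with it broken. Observed betas add Gaussian noise;
#' p-values are one-sided normal tails on beta / noise-sd. Decoy trans and
#' far-distance records are appended for filter testing.
#'
#' @param sim A `cc_sim_genome`.
#' @param cfg The `SimConfig`.
#' @param study_cell,study_mark Index of the cell/mark the simulated
#'   association study measured.
#' @param seed Seed (defaults to `cfg$seed`).
#' @return List with `variants` (data frame: id, chrom, pos (0-based), ref,
#'   alt), `records` (hQTL association records), `truth` (variant id, true
#'   signed effect, record type).
#' @export
simulate_hqtl <- function(sim, cfg, study_cell = 1L, study_mark = 1L,
                          seed = cfg$seed) {
  g <- sim$grammar
  occ <- sim$occurrences
  active <- g$usage[study_cell, occ$motif] > 0
  cand <- occ[active, , drop = FALSE]
  if (nrow(cand) < 1) stop("chromcast_error: no candidate sites for hQTLs")
  nn_seeded(seed + 4000L, {
    n <- min(cfg$n_hqtl, nrow(cand))
    pick <- cand[sample.int(nrow(cand), n), , drop = FALSE]
    sigma <- g$peak_halfwidth
    vars <- list(); recs <- list(); truth <- list()
    for (i in seq_len(n)) {
      row <- pick[i, ]
      mot <- g$motifs[row$motif]
      written <- if (row$strand == "+") mot else revcomp_chr(mot)
      wchars <- strsplit(written, "")[[1]]
      mlen <- length(wchars)
      seqchars <- substring(sim$sequences[[row$chrom]],
                            row$motif_start + 1, row$motif_start + mlen)
      seqchars <- strsplit(seqchars, "")[[1]]
      if (row$intact) {
        off <- (mlen + 1L) %/% 2L
        ref <- seqchars[off]
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        sgn <- -1
      } else {
        off <- row$lesion_offset
        ref <- seqchars[off]
        alt <- row$lesion_consensus_base
        sgn <- +1
      }
      amp <- g$peak_amp * g$usage[study_cell, row$motif] *
        g$affinity[row$motif, study_mark]
      effect <- sgn * amp
      id <- sprintf("rs%05d", i)
      pos <- row$motif_start + off - 1L     # 0-based variant position
      vars[[i]] <- data.frame(id = id, chrom = row$chrom, pos = pos,
                              ref = ref, alt = alt)
      beta <- effect + stats::rnorm(1, 0, cfg$hqtl_noise_sd)
      recs[[i]] <- data.frame(
        id = id, chrom = row$chrom, pos = pos,
        peak_chrom = row$chrom,
        peak_start = max(0, floor(row$centre - 3 * sigma)),
        peak_end = min(cfg$chrom_len, ceiling(row$centre + 3 * sigma)),
        beta = beta,
        p = max(stats::pnorm(-abs(beta) / max(cfg$hqtl_noise_sd, 1e-9)),
                1e-300))
      truth[[i]] <- data.frame(id = id, true_effect = effect,
                               type = "causal")
    }
    variants <- do.call(rbind, vars)
    records <- do.call(rbind, recs)
    truthdf <- do.call(rbind, truth)
    # decoys reuse causal variants with displaced peaks
    mk_decoy <- function(k, type) {
      src <- records[sample.int(nrow(records), k, replace = TRUE), ]
      src$id <- sprintf("rs_%s%02d", substr(type, 1, 1), seq_len(k))
      for (j in seq_len(k)) {
        if (type == "trans") {
          others <- setdiff(sim$genome$names, src$chrom[j])
          src$peak_chrom[j] <- if (length(others)) others[1] else src$chrom[j]
        } else {
          shift_to <- if (src$pos[j] < cfg$chrom_len / 2)
            cfg$chrom_len - 6000 else 1000
          w <- src$peak_end[j] - src$peak_start[j]
          src$peak_start[j] <- shift_to
          src$peak_end[j] <- shift_to + w
        }
        src$beta[j] <- stats::rnorm(1, 0, cfg$hqtl_noise_sd)
        src$p[j] <- stats::runif(1, 0.2, 1)
      }
      src
    }
    if (cfg$n_trans_decoys > 0 && cfg$n_chrom > 1) {
      d <- mk_decoy(cfg$n_trans_decoys, "trans")
      records <- rbind(records, d)
      truthdf <- rbind(truthdf, data.frame(id = d$id, true_effect = 0,
                                           type = "trans"))
    }
    if (cfg$n_far_decoys > 0) {
      d <- mk_decoy(cfg$n_far_decoys, "far")
      records <- rbind(records, d)
      truthdf <- rbind(truthdf, data.frame(id = d$id, true_effect = 0,
                                           type = "far"))
    }
    list(variants = variants, records = records, truth = truthdf,
         study_cell = g$cells[study_cell], study_mark = g$marks[study_mark])
  })
}
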