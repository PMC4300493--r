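# A hand-built gene whose single 150-nt window has exactly 25 A/C
# nucleotides: k = ceil(0.05 * 25) = 2, so the top-5% set is the two highest
# A/C counts (plus ties).
handbuilt_dms <- function(ac_counts, gt_count = 10) {
  stopifnot(length(ac_counts) == 25)
  bases <- rep("G", 150)
  ac_pos <- seq(1, by = 6, length.out = 25)  # 25 scattered A positions
  bases[ac_pos] <- "A"
  genes <- tibble::tibble(gene_id = "g",
                          cds = paste(bases, collapse = ""))
  counts <- rep(gt_count, 150)
  counts[ac_pos] <- ac_counts
  tracks <- tibble::tibble(gene_id = "g", position = 0:149, count = counts)
  list(genes = genes, tracks = tracks, ac_pos0 = ac_pos - 1L)
}

test_that("DMS normalisation divides by the top-5% minimum and caps at 1", {
  # top two A/C counts are 100 and 80 -> divisor 80; 40 -> 0.5; both top -> 1
  ac <- c(100, 80, 40, rep(8, 22))
  hb <- handbuilt_dms(ac)
  norm <- normalize_dms(hb$tracks, hb$genes)
  r <- norm$reactivity
  expect_equal(r$reactivity[r$position == hb$ac_pos0[1]], 1)
  expect_equal(r$reactivity[r$position == hb$ac_pos0[2]], 1)
  expect_equal(r$reactivity[r$position == hb$ac_pos0[3]], 0.5)
  expect_equal(r$reactivity[r$position == hb$ac_pos0[4]], 0.1)
  # everything in [0, 1]
  expect_true(all(r$reactivity >= 0 & r$reactivity <= 1, na.rm = TRUE))
  expect_false(any(norm$window_log$masked))
})

test_that("DMS masking rules fire exactly as specified", {
  # fewer than 10 A/C nucleotides in the window -> fully masked
  bases <- rep("G", 150)
  bases[seq(1, by = 18, length.out = 8)] <- "A"  # only 8 A/C positions
  genes <- tibble::tibble(gene_id = "g", cds = paste(bases, collapse = ""))
  tracks <- tibble::tibble(gene_id = "g", position = 0:149,
                           count = rep(50, 150))
  norm <- normalize_dms(tracks, genes)
  expect_true(all(norm$reactivity$masked))
  expect_equal(norm$window_log$reason, "too_few_ac")

  # all-zero counts -> zero normalisation constant -> masked
  hb <- handbuilt_dms(rep(0, 25), gt_count = 0)
  norm2 <- normalize_dms(hb$tracks, hb$genes)
  expect_true(all(norm2$reactivity$masked))
  expect_equal(norm2$window_log$reason, "zero_divisor")

  # a gene shorter than one window is a single whole-gene window
  short <- tibble::tibble(gene_id = "s", cds = "ATGAAACCCAAACCCAAATAA")
  tr <- tibble::tibble(gene_id = "s", position = 0:20, count = 5)
  norm3 <- normalize_dms(tr, short)
  expect_equal(nrow(norm3$window_log), 1)
})

test_that("window profiles normalise per gene and average across genes", {
  # constant signal per gene -> every normalised window = 1 -> flat profile
  tr <- tibble::tibble(gene_id = "g", position = -40:299, value = 3)
  wp <- window_profile(tr, width = 40, upstream = 30, downstream = 250)
  expect_equal(unique(wp$profile$mean), 1)
  expect_equal(nrow(wp$profile), 280)

  # single gene: profile equals its own normalised windows
  withr::with_seed(12, {
    tr2 <- tibble::tibble(gene_id = "g", position = -40:299,
                          value = runif(340, 1, 2))
  })
  wp2 <- window_profile(tr2, width = 40, upstream = 30, downstream = 250)
  pg <- wp2$per_gene[!is.na(wp2$per_gene$value), ]
  expect_equal(wp2$profile$mean, pg$value)

  # two genes with opposite linear trends of equal magnitude (centred so the
  # per-gene window means coincide) -> exactly flat mean profile
  pos <- -40:299
  up <- tibble::tibble(gene_id = "up", position = pos,
                       value = 10 + 0.01 * (pos - 129))
  dn <- tibble::tibble(gene_id = "dn", position = pos,
                       value = 10 - 0.01 * (pos - 129))
  wp3 <- window_profile(dplyr::bind_rows(up, dn), width = 40,
                        upstream = 30, downstream = 250)
  expect_equal(wp3$profile$mean, rep(1, 280))
})

test_that("TE-window correlation applies the Bonferroni factor", {
  # planted: window value at position 0 monotone in TE
  withr::with_seed(13, {
    n_genes <- 60
    te <- tibble::tibble(gene_id = sprintf("g%02d", 1:n_genes),
                         te = exp(rnorm(n_genes)))
    tracks <- purrr::map_dfr(seq_len(n_genes), function(i) {
      base <- runif(120, 0.8, 1.2)
      sig <- rep(log(te$te[i]), 40)  # nt 0..39 carry the TE signal
      tibble::tibble(gene_id = te$gene_id[i], position = 0:119,
                     value = base + c(sig, rep(0, 80)))
    })
  })
  wp <- window_profile(tracks, width = 40, upstream = 0, downstream = 80)
  res <- te_window_correlation(wp, te)
  r0 <- res[res$position == 0, ]
  expect_gt(r0$rho, 0)
  expect_lt(r0$p_corrected, 0.05)
  # correction arithmetic: p_corrected = min(1, p_raw * n_windows)
  expect_equal(res$p_corrected,
               pmin(1, res$p_raw * (wp$upstream + wp$downstream)))
  # a raw p of 0.01 with 280 windows is not significant
  expect_equal(min(1, 0.01 * 280), 1)
})

test_that("energy dip detection finds the first local minimum", {
  # unique global minimum at +60
  prof <- tibble::tibble(position = -30:249,
                         mean = 1 + ((-30:249) - 60)^2 / 1e4)
  expect_equal(find_energy_dip(prof), 60L)
  # two 90-nt-span minima at +60 and +200, the second deeper (the global
  # minimum): the first wins
  pos <- -30:249
  v <- ifelse(pos <= 130, 0.001 * abs(pos - 60),
              0.001 * abs(pos - 200) - 0.05)
  prof2 <- tibble::tibble(position = pos, mean = v)
  expect_equal(which.min(v), which(pos == 200))
  expect_equal(find_energy_dip(prof2), 60L)
  # strictly increasing profile: first scanned position
  prof3 <- tibble::tibble(position = pos, mean = seq_along(pos))
  expect_equal(find_energy_dip(prof3), 0L)
  # invariant to adding a constant
  expect_equal(find_energy_dip(dplyr::mutate(prof, mean = mean + 100)), 60L)
})

test_that("the simulated DMS pipeline recovers a planted structure band", {
  genes <- simulate_genome(30, mean_len = 150, utr5_len = 40, seed = 9)
  acc <- function(pos) ifelse(pos >= 60 & pos < 100, 0.15, 0.8)
  tracks <- simulate_dms_counts(genes, accessibility = acc, depth = 50,
                                seed = 10)
  norm <- normalize_dms(tracks, genes)
  r <- norm$reactivity$reactivity
  expect_true(all(r[!is.na(r)] >= 0 & r[!is.na(r)] <= 1))
  aligned <- align_to_start(norm, genes)
  wp <- window_profile(aligned, width = 40, upstream = 30, downstream = 250)
  dip <- find_energy_dip(wp)
  expect_gte(dip, 40)
  expect_lte(dip, 120)
  expect_s3_class(autoplot(wp), "ggplot")

  # accessibility 1 at high depth: reactivities cluster near 1
  tracks2 <- simulate_dms_counts(genes[1:5, ],
                                 accessibility = function(p) rep(1, length(p)),
                                 depth = 200, seed = 11)
  norm2 <- normalize_dms(tracks2, genes[1:5, ])
  ac <- norm2$reactivity[norm2$reactivity$base %in% c("A", "C") &
                           !is.na(norm2$reactivity$reactivity), ]
  expect_gt(median(ac$reactivity), 0.8)

  # zero depth: all windows masked by the zero divisor
  tracks0 <- dplyr::mutate(tracks, count = 0)
  norm0 <- normalize_dms(tracks0, genes)
  expect_true(all(norm0$reactivity$masked))
})
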