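#' Fit abundance-binned noise scales for outlier detection
#'
#' Genes are divided into abundance quantile bins (abundance = the per-gene
#' mean footprint count D_m) and, for each (bin, codon) cell, the sample
#' standard deviation of the scaled counts (pseudo-counted, single global
#' factor — the same axis as flux expectations) is computed. The requested
#' number of bins is reduced automatically to the largest value for which
#' every cell has at least three counts and a nonzero standard deviation.
#'
#' @param fit A `flow_fit` object.
#' @param n_bins Requested number of abundance quantile bins (default 32).
#' @return An object of class `noise_bins`: tibble `sd_table` (bin, codon,
#'   sd, n), `gene_bins` (gene_id, bin), `n_bins` actually used, and
#'   `n_bins_requested`.
#' @export
fit_noise_bins <- function(fit, n_bins = 32L) {
  stopifnot(inherits(fit, "flow_fit"), n_bins >= 1)
  d <- fit$transform$data
  gm <- fit$transform$gene_means

  try_bins <- function(nb) {
    # quantile bins over gene abundance; ties collapse bins via unique breaks
    br <- unique(stats::quantile(gm$D, probs = seq(0, 1, length.out = nb + 1)))
    bins <- cut(gm$D, breaks = br, include.lowest = TRUE, labels = FALSE)
    gene_bins <- tibble::tibble(gene_id = gm$gene_id, bin = bins)
    sd_table <- d %>%
      dplyr::left_join(gene_bins, by = "gene_id") %>%
      dplyr::group_by(.data$bin, .data$codon) %>%
      dplyr::summarise(sd = stats::sd(.data$dscaled), n = dplyr::n(),
                       .groups = "drop")
    ok <- all(sd_table$n >= 3) && all(sd_table$sd > 0) &&
      length(br) == nb + 1
    list(ok = ok, sd_table = sd_table, gene_bins = gene_bins)
  }

  for (nb in seq(as.integer(n_bins), 1L)) {
    res <- try_bins(nb)
    if (res$ok) {
      return(structure(list(sd_table = res$sd_table,
                            gene_bins = res$gene_bins,
                            n_bins = nb, n_bins_requested = as.integer(n_bins)),
                       class = "noise_bins"))
    }
  }
  stop("no feasible number of abundance bins >= 1 ",
       "(some codon has < 3 counts or constant counts overall)", call. = FALSE)
}

#' Outlier strength of a position
#'
#' The standardised deviation of the observed (scaled) count from its model
#' expectation: \eqn{\Delta = (d' - J\mu)/s}.
#'
#' @param observed Observed scaled count(s).
#' @param expected Expected count(s) \eqn{J_m \mu_m^c}.
#' @param s Noise scale(s) from [fit_noise_bins()]; must be positive.
#' @return Numeric vector of outlier strengths.
#' @export
#' @examples
#' outlier_strength(9, 3, 2)  # 3
outlier_strength <- function(observed, expected, s) {
  if (any(s <= 0)) stop("noise scale s must be positive", call. = FALSE)
  (observed - expected) / s
}

#' Compute outlier strengths for every position
#'
#' Joins model expectations (flux times per-gene codon dwell, falling back
#' to the global dwell outside the restricted region) with the binned noise
#' scales and returns per-position outlier strengths.
#'
#' @param fit A `flow_fit` object (fitted fluxes required).
#' @param bins A `noise_bins` object; fitted from `fit` when `NULL`.
#' @return Tibble `gene_id`, `position`, `codon`, `observed`, `expected`,
#'   `s`, `delta`.
#' @export
outlier_deltas <- function(fit, bins = NULL) {
  stopifnot(inherits(fit, "flow_fit"))
  if (is.null(bins)) bins <- fit_noise_bins(fit)
  d <- fit$transform$data
  mu <- global_dwell_lookup(fit, d$codon)
  if (!is.null(fit$dwell_gene)) {
    idx <- match(paste(d$gene_id, d$codon),
                 paste(fit$dwell_gene$gene_id, fit$dwell_gene$codon))
    mu <- ifelse(is.na(idx), mu, fit$dwell_gene$mu[idx])
  }
  J <- fit$flows$J[match(d$gene_id, fit$flows$gene_id)]
  out <- tibble::tibble(
    gene_id = d$gene_id, position = d$position, codon = d$codon,
    observed = d$dscaled, expected = J * mu
  ) %>%
    dplyr::left_join(bins$gene_bins, by = "gene_id") %>%
    dplyr::left_join(bins$sd_table[, c("bin", "codon", "sd")],
                     by = c("bin", "codon")) %>%
    dplyr::rename(s = "sd")
  out$delta <- outlier_strength(out$observed, out$expected, out$s)
  dplyr::select(out, -"bin")
}

#' Classify positions as slow outliers or non-outliers
#'
#' A slow outlier is a position with \eqn{\Delta > T}; non-outliers satisfy
#' \eqn{-1 < \Delta < 1} (and are not slow outliers). Everything else —
#' notably candidate fast outliers, which may be artefacts of A-site
#' misattribution — is excluded from comparisons.
#'
#' @param deltas Tibble with a `delta` column (e.g. from [outlier_deltas()]),
#'   or a numeric vector.
#' @param T Slow-outlier threshold (default 1).
#' @return The input tibble with a `class` column (`"slow"`,
#'   `"non_outlier"`, `"excluded"`), or a character vector for vector input.
#' @export
classify_outliers <- function(deltas, T = 1) {
  cls <- function(delta) {
    dplyr::case_when(
      delta > T ~ "slow",
      delta > -1 & delta < 1 ~ "non_outlier",
      TRUE ~ "excluded"
    )
  }
  if (is.numeric(deltas)) return(cls(deltas))
  dplyr::mutate(deltas, class = cls(.data$delta))
}

#' Evaluate a candidate feature against outlier strength
#'
#' A feature is called significant only under a stringent set of criteria:
#' (a) among slow outliers, Pearson and Spearman correlations between the
#' feature and outlier strength share one sign and are significant
#' (p < `alpha`) at every threshold in `thresholds`; (b) the per-codon
#' correlation (computed among slow outliers at the smallest threshold,
#' restricted to each codon) is significant for at least `min_codons`
#' codons; (c) the common correlation sign matches the direction of the
#' slow-versus-non-outlier comparison of feature means.
#'
#' @param deltas Tibble with `delta`, `codon` and the feature column.
#' @param feature Name of the feature column (string).
#' @param thresholds Slow-outlier thresholds (default 0, 0.5, ..., 2.5).
#' @param alpha Significance level (default 0.05).
#' @param min_codons Minimum number of significant per-codon correlations
#'   (default 30).
#' @return A list of class `feature_verdict`: `significant` (logical or NA
#'   for insufficient data), `verdict` string, `by_threshold` tibble,
#'   `n_significant_codons`, `mean_comparison` list.
#' @export
feature_significance <- function(deltas, feature,
                                 thresholds = c(0, 0.5, 1, 1.5, 2, 2.5),
                                 alpha = 0.05, min_codons = 30L) {
  stopifnot(feature %in% names(deltas), "delta" %in% names(deltas))
  fvals <- deltas[[feature]]
  if (any(is.na(fvals))) stop("feature must be defined on all positions", call. = FALSE)

  by_threshold <- purrr::map_dfr(thresholds, function(T) {
    slow <- deltas[deltas$delta > T, , drop = FALSE]
    if (nrow(slow) < 2) {
      return(tibble::tibble(threshold = T, n = nrow(slow),
                            pearson_r = NA_real_, pearson_p = NA_real_,
                            spearman_r = NA_real_, spearman_p = NA_real_))
    }
    pe <- suppressWarnings(stats::cor.test(slow[[feature]], slow$delta,
                                           method = "pearson"))
    sp <- suppressWarnings(stats::cor.test(slow[[feature]], slow$delta,
                                           method = "spearman", exact = FALSE))
    tibble::tibble(threshold = T, n = nrow(slow),
                   pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                   spearman_r = unname(sp$estimate), spearman_p = sp$p.value)
  })

  if (any(by_threshold$n < 2)) {
    return(structure(list(significant = NA, verdict = "insufficient data",
                          by_threshold = by_threshold,
                          n_significant_codons = NA_integer_,
                          mean_comparison = NULL),
                     class = "feature_verdict"))
  }

  signs <- sign(c(by_threshold$pearson_r, by_threshold$spearman_r))
  same_sign <- length(unique(signs)) == 1 && all(signs != 0)
  all_sig <- all(by_threshold$pearson_p < alpha) &&
    all(by_threshold$spearman_p < alpha)
  crit_a <- same_sign && all_sig

  slow0 <- deltas[deltas$delta > min(thresholds), , drop = FALSE]
  per_codon <- slow0 %>%
    dplyr::group_by(.data$codon) %>%
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 3 || stats::sd(g[[feature]]) == 0 || stats::sd(g$delta) == 0) {
        return(tibble::tibble(r = NA_real_, p = NA_real_, n = nrow(g)))
      }
      ct <- suppressWarnings(stats::cor.test(g[[feature]], g$delta,
                                             method = "spearman", exact = FALSE))
      tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(g))
    }) %>%
    dplyr::ungroup()
  n_sig_codons <- sum(per_codon$p < alpha, na.rm = TRUE)
  crit_b <- n_sig_codons >= min_codons

  cls <- classify_outliers(deltas, T = min(thresholds))
  mean_slow <- mean(cls[[feature]][cls$class == "slow"])
  mean_non <- mean(cls[[feature]][cls$class == "non_outlier"])
  mean_dir <- sign(mean_slow - mean_non)
  crit_c <- isTRUE(mean_dir == signs[1])

  significant <- crit_a && crit_b && crit_c
  structure(list(
    significant = significant,
    verdict = if (significant) "significant" else "not significant",
    by_threshold = by_threshold,
    n_significant_codons = as.integer(n_sig_codons),
    per_codon = per_codon,
    mean_comparison = list(mean_slow = mean_slow, mean_non_outlier = mean_non,
                           direction = mean_dir, matches_correlation = crit_c)
  ), class = "feature_verdict")
}

#' @export
print.feature_verdict <- function(x, ...) {
  cat("<feature_verdict> ", x$verdict, "\n", sep = "")
  if (!is.na(x$significant)) {
    cat("  significant codons: ", x$n_significant_codons, "\n", sep = "")
  }
  invisible(x)
}

#' Position features for outlier analysis
#'
#' The built-in positional covariates: distance from the 5' end (`k`),
#' relative position (`k/L`), and distance from the 3' end (`L-k`).
#'
#' @param deltas Tibble with `gene_id` and `position`.
#' @param genes Gene table used to obtain lengths.
#' @return `deltas` with columns `pos_from_5p`, `rel_pos`, `pos_from_3p`.
#' @export
position_features <- function(deltas, genes) {
  L <- tibble::tibble(gene_id = genes$gene_id,
                      L = purrr::map_int(genes$cds, gene_length_codons))
  deltas %>%
    dplyr::left_join(L, by = "gene_id") %>%
    dplyr::mutate(pos_from_5p = .data$position,
                  rel_pos = .data$position / .data$L,
                  pos_from_3p = .data$L - .data$position) %>%
    dplyr::select(-"L")
}

#' Kolmogorov–Smirnov test on relative outlier positions
#'
#' Two-sample KS test comparing the distributions of relative positions
#' (k/L) of outliers between two gene groups (e.g. reduced-TE versus
#' increased-TE genes).
#'
#' @param group_a,group_b Numeric vectors of relative positions in `[0, 1]`.
#' @return One-row tibble `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
ks_position_test <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(group_a, group_b))
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
                 n_a = length(group_a), n_b = length(group_b))
}
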