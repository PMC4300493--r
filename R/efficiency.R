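#' Translation efficiency from fluxes and mRNA abundance
#'
#' Translation efficiency of gene m is its protein synthesis rate divided by
#' its mRNA transcript level: \eqn{TE_m = J_m / M_m}. Only genes present in
#' both tables are returned; genes with non-positive abundance are skipped
#' with a warning.
#'
#' @param flows Tibble `gene_id`, `J` (e.g. `fit$flows`), or a `flow_fit`.
#' @param abundance Tibble `gene_id`, `abundance`.
#' @return Tibble `gene_id`, `te`.
#' @export
compute_te <- function(flows, abundance) {
  if (inherits(flows, "flow_fit")) flows <- flows$flows
  df <- dplyr::inner_join(flows, abundance, by = "gene_id")
  bad <- df$abundance <= 0 | is.na(df$abundance)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with non-positive mRNA abundance skipped")
    df <- df[!bad, , drop = FALSE]
  }
  dplyr::transmute(df, gene_id = .data$gene_id, te = .data$J / .data$abundance)
}

#' Per-codon correlation between TE change and codon content
#'
#' For each sense codon, the Spearman correlation across genes between the
#' mutant/wild-type TE ratio and the fraction of the gene's codons that are
#' that codon. A codon whose cognate tRNA was depleted is expected to show a
#' negative correlation if the depletion reduces efficiency of the genes
#' using it.
#'
#' @param te_wt,te_mut Tibbles `gene_id`, `te` for the two samples; genes
#'   are intersected.
#' @param genes Gene table (`gene_id`, `cds`) providing codon content.
#' @param alpha Significance level for flagging codons (default 0.05).
#' @return Tibble `codon`, `rho`, `p_value`, `significant`, `n_genes`.
#'   Correlations undefined (e.g. constant ratio) are NA.
#' @export
per_codon_te_correlation <- function(te_wt, te_mut, genes, alpha = 0.05) {
  shared <- dplyr::inner_join(te_wt, dplyr::rename(te_mut, te_mut = "te"),
                              by = "gene_id")
  if (nrow(shared) < 10) stop("need >= 10 shared genes", call. = FALSE)
  shared$ratio <- shared$te_mut / shared$te
  frac <- codon_table(genes) %>%
    dplyr::filter(.data$gene_id %in% shared$gene_id) %>%
    dplyr::count(.data$gene_id, .data$codon) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(frac = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  codons <- sort(unique(frac$codon))
  purrr::map_dfr(codons, function(cod) {
    f <- frac[frac$codon == cod, c("gene_id", "frac")]
    df <- shared %>%
      dplyr::left_join(f, by = "gene_id") %>%
      dplyr::mutate(frac = dplyr::coalesce(.data$frac, 0))
    if (stats::sd(df$ratio) == 0 || stats::sd(df$frac) == 0) {
      return(tibble::tibble(codon = cod, rho = NA_real_, p_value = NA_real_,
                            significant = NA, n_genes = nrow(df)))
    }
    ct <- suppressWarnings(stats::cor.test(df$ratio, df$frac,
                                           method = "spearman", exact = FALSE))
    tibble::tibble(codon = cod, rho = unname(ct$estimate),
                   p_value = ct$p.value,
                   significant = ct$p.value < alpha, n_genes = nrow(df))
  })
}

#' Count reduced versus increased TE genes among the top deviators
#'
#' Ranks shared genes by the absolute log ratio of mutant to wild-type TE,
#' takes the `n` most deviating (ties at the cut broken by gene id), and
#' counts how many have lower mutant TE (`reduced`) versus higher
#' (`increased`; a log ratio of exactly 0 counts as increased, which cannot
#' occur among genuine deviators).
#'
#' @param te_wt,te_mut Tibbles `gene_id`, `te`.
#' @param n Number of top deviating genes (default 200).
#' @return One-row tibble `reduced`, `increased`, `n`, plus the `top_genes`
#'   tibble as an attribute (`gene_id`, `log_ratio`).
#' @export
top_deviating_counts <- function(te_wt, te_mut, n = 200L) {
  shared <- dplyr::inner_join(te_wt, dplyr::rename(te_mut, te_mut = "te"),
                              by = "gene_id")
  if (n > nrow(shared)) {
    stop("n = ", n, " exceeds the ", nrow(shared), " shared genes", call. = FALSE)
  }
  shared <- shared %>%
    dplyr::mutate(log_ratio = log(.data$te_mut / .data$te)) %>%
    dplyr::arrange(dplyr::desc(abs(.data$log_ratio)), .data$gene_id) %>%
    dplyr::slice_head(n = n)
  reduced <- sum(shared$log_ratio < 0)
  out <- tibble::tibble(reduced = reduced, increased = n - reduced, n = n)
  attr(out, "top_genes") <- shared[, c("gene_id", "log_ratio")]
  out
}

#' Permutation test for the reduced-versus-increased TE imbalance
#'
#' Permutes the mutant TE values across genes `n_perm` times, recomputing
#' the difference (reduced minus increased) among the top `n` deviating
#' genes for each permutation. The reported p-value is the fraction of
#' permutations whose difference is at least the observed one (a one-sided
#' test for an excess of reduced-TE genes); the count of permutations with a
#' smaller difference is also reported.
#'
#' @param te_wt,te_mut Tibbles `gene_id`, `te`.
#' @param n Number of top deviating genes (default 200).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return One-row tibble `observed_diff`, `reduced`, `increased`,
#'   `p_value`, `n_less`, `n_perm`.
#' @export
te_permutation_test <- function(te_wt, te_mut, n = 200L, n_perm = 1000L,
                                seed = 1L) {
  obs <- top_deviating_counts(te_wt, te_mut, n)
  obs_diff <- obs$reduced - obs$increased
  shared <- dplyr::inner_join(te_wt, dplyr::rename(te_mut, te_mut = "te"),
                              by = "gene_id")
  wt <- shared$te
  mut <- shared$te_mut
  perm_diff <- withr::with_seed(seed, {
    purrr::map_dbl(seq_len(n_perm), function(i) {
      pm <- sample(mut)
      lr <- log(pm / wt)
      ord <- order(-abs(lr))[seq_len(n)]
      reduced <- sum(lr[ord] < 0)
      reduced - (n - reduced)
    })
  })
  tibble::tibble(
    observed_diff = obs_diff,
    reduced = obs$reduced, increased = obs$increased,
    p_value = mean(perm_diff >= obs_diff),
    n_less = sum(perm_diff < obs_diff),
    n_perm = n_perm
  )
}
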