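# Synthetic data with known ground truth. Defaults encode the stated world
# used throughout the tests: 200 genes of ~300 codons, Poisson footprint
# sampling at a mean of 20 counts/codon, lognormal codon dwell spread
# (sdlog 0.4, a severalfold rate range), per-gene dwell variation sdlog 0.2,
# lognormal fluxes (sdlog 0.5) and mRNA abundances (sdlog 1).

#' Simulate a synthetic genome
#'
#' Generates coding sequences that pass every gene filter: each starts with
#' ATG, ends with a stop codon, and contains no internal stop. Body codons
#' are drawn i.i.d. from `codon_bias` over the 61 sense codons. Lengths (in
#' coding codons) are drawn from a discretised lognormal around `mean_len`.
#' A 5' UTR of `utr5_len` random nt supplies the Kozak context.
#'
#' @param n_genes Number of genes.
#' @param mean_len Mean gene length in codons (default 300).
#' @param sdlog_len Lognormal sdlog of lengths (default 0.3); lengths are
#'   floored at `min_len`.
#' @param min_len Minimum length in codons (default 60).
#' @param codon_bias Named probability vector over [sense_codons()];
#'   default uniform. Mass on stop codons is an error.
#' @param utr5_len,utr3_len UTR lengths in nt (defaults 30, 30).
#' @param seed Integer seed.
#' @return Gene tibble: `gene_id`, `cds` (with terminal stop), `utr5`,
#'   `utr3`, `kozak_context`.
#' @export
simulate_genome <- function(n_genes, mean_len = 300, sdlog_len = 0.3,
                            min_len = 60L, codon_bias = NULL,
                            utr5_len = 30L, utr3_len = 30L, seed = 1L) {
  sc <- sense_codons()
  if (is.null(codon_bias)) {
    codon_bias <- stats::setNames(rep(1 / 61, 61), sc)
  }
  if (any(names(codon_bias) %in% STOP_CODONS)) {
    stop("codon_bias must not place mass on stop codons", call. = FALSE)
  }
  if (!all(names(codon_bias) %in% sc)) {
    stop("codon_bias names must be sense codons", call. = FALSE)
  }
  bias <- stats::setNames(rep(0, 61), sc)
  bias[names(codon_bias)] <- codon_bias
  bias <- bias / sum(bias)
  withr::with_seed(seed, {
    lens <- pmax(min_len,
                 round(stats::rlnorm(n_genes, log(mean_len) - sdlog_len^2 / 2,
                                     sdlog_len)))
    ids <- sprintf("g%04d", seq_len(n_genes))
    bases <- c("A", "C", "G", "T")
    tibble::tibble(
      gene_id = ids,
      cds = purrr::map_chr(lens, function(L) {
        body <- sample(sc, L - 1L, replace = TRUE, prob = bias)
        paste0("ATG", paste(body, collapse = ""),
               sample(STOP_CODONS, 1))
      }),
      utr5 = purrr::map_chr(seq_len(n_genes), ~ paste(
        sample(bases, utr5_len, replace = TRUE), collapse = "")),
      utr3 = purrr::map_chr(seq_len(n_genes), ~ paste(
        sample(bases, utr3_len, replace = TRUE), collapse = ""))
    ) %>%
      dplyr::mutate(kozak_context = paste0(
        substr(.data$utr5, utr5_len - 5L, utr5_len),
        substr(.data$cds, 1L, 6L)))
  })
}

#' Simulate ground-truth translation parameters
#'
#' Draws global codon dwell times, per-gene dwell deviations, fluxes and
#' mRNA abundances, and optionally injects pause sites (positions whose
#' dwell is multiplied by `pause_fold`).
#'
#' @param genes Gene tibble from [simulate_genome()].
#' @param sdlog_mu Lognormal spread of global codon dwells (default 0.4).
#' @param sdlog_gene Per-gene dwell spread around the global dwell (default
#'   0.2).
#' @param sdlog_J Lognormal spread of fluxes (default 0.5).
#' @param sdlog_M Lognormal spread of mRNA abundances (default 1).
#' @param pause_per_gene Number of injected pause sites per gene (default
#'   0), placed uniformly in the gene body.
#' @param pause_fold Dwell multiplier at pause sites (default 10).
#' @param pause_region Restrict pause placement to positions in
#'   `[pause_region[1], pause_region[2])` relative codon fraction (default
#'   whole gene, `c(0, 1)`); use e.g. `c(0, 0.3)` for 5'-enriched pauses.
#' @param seed Integer seed.
#' @return A list of class `sim_truth`: `genes`, `mu_global` (codon, mu,
#'   mean 1), `mu_gene` (gene_id, codon, mu), `J` (gene_id, J, mean 1),
#'   `abundance` (gene_id, abundance), `pause_sites` (gene_id, position,
#'   fold), `seed`.
#' @export
simulate_truth <- function(genes, sdlog_mu = 0.4, sdlog_gene = 0.2,
                           sdlog_J = 0.5, sdlog_M = 1,
                           pause_per_gene = 0L, pause_fold = 10,
                           pause_region = c(0, 1), seed = 1L) {
  stopifnot(pause_fold >= 1)
  ct <- codon_table(genes)
  sc <- sense_codons()
  withr::with_seed(seed, {
    mu_g <- stats::rlnorm(61, 0, sdlog_mu)
    mu_g <- mu_g / mean(mu_g)
    mu_global <- tibble::tibble(codon = sc, mu = mu_g)
    mu_gene <- ct %>%
      dplyr::distinct(.data$gene_id, .data$codon) %>%
      dplyr::mutate(
        mu = mu_g[match(.data$codon, sc)] *
          stats::rlnorm(dplyr::n(), -sdlog_gene^2 / 2, sdlog_gene))
    J <- stats::rlnorm(nrow(genes), 0, sdlog_J)
    J <- J / mean(J)
    M <- stats::rlnorm(nrow(genes), 0, sdlog_M)
    pause_sites <- if (pause_per_gene > 0) {
      purrr::map_dfr(seq_len(nrow(genes)), function(i) {
        L <- gene_length_codons(genes$cds[i])
        lo <- floor(pause_region[1] * L)
        hi <- max(lo + 1, ceiling(pause_region[2] * L) - 1)
        k <- sample(seq.int(lo, hi), min(pause_per_gene, hi - lo + 1))
        tibble::tibble(gene_id = genes$gene_id[i], position = as.integer(k),
                       fold = pause_fold)
      })
    } else {
      tibble::tibble(gene_id = character(), position = integer(),
                     fold = double())
    }
    structure(list(
      genes = genes, mu_global = mu_global, mu_gene = mu_gene,
      J = tibble::tibble(gene_id = genes$gene_id, J = J),
      abundance = tibble::tibble(gene_id = genes$gene_id, abundance = M),
      pause_sites = pause_sites, seed = seed
    ), class = "sim_truth")
  })
}

#' Simulate footprint profiles from ground truth
#'
#' Observed footprint counts follow the generative inverse of the
#' steady-state flow model: at position (m, k) with codon c,
#' \eqn{d_{mk} \sim Poisson(depth \cdot J_m \cdot \mu_m^c \cdot fold_{mk})},
#' so slower positions accumulate proportionally more footprints. mRNA
#' counts are uniform along the gene, Poisson at a rate proportional to the
#' gene's abundance.
#'
#' @param truth A `sim_truth` object.
#' @param depth Mean footprint count per codon (fluxes and dwells have mean
#'   1, so `depth` is the genome-wide expected count; default 20).
#' @param mrna_depth Mean mRNA count per codon position (default 10).
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `position`, `codon`, `count`, `mrna_count`.
#' @export
simulate_footprints <- function(truth, depth = 20, mrna_depth = 10,
                                seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"), depth >= 0)
  ct <- codon_table(truth$genes)
  d <- ct %>%
    dplyr::left_join(truth$mu_gene, by = c("gene_id", "codon")) %>%
    dplyr::left_join(truth$J, by = "gene_id") %>%
    dplyr::left_join(truth$abundance, by = "gene_id")
  if (nrow(truth$pause_sites) > 0) {
    d <- d %>%
      dplyr::left_join(truth$pause_sites, by = c("gene_id", "position")) %>%
      dplyr::mutate(fold = dplyr::coalesce(.data$fold, 1))
  } else {
    d$fold <- 1
  }
  withr::with_seed(seed, {
    d$count <- stats::rpois(nrow(d), depth * d$J * d$mu * d$fold)
    mean_M <- mean(truth$abundance$abundance)
    d$mrna_count <- stats::rpois(nrow(d), mrna_depth * d$abundance / mean_M)
  })
  dplyr::select(d, "gene_id", "position", "codon", "count", "mrna_count")
}

#' Simulate a complete ribosome profiling dataset
#'
#' Convenience wrapper chaining [simulate_genome()], [simulate_truth()] and
#' [simulate_footprints()] with a single seed.
#'
#' @param n_genes,mean_len,depth Dataset dimensions (defaults 200 genes,
#'   300 codons, 20 counts/codon).
#' @param seed Integer seed; sub-seeds for genome, truth and sampling are
#'   derived from it.
#' @param ... Passed to [simulate_truth()] (dwell spreads, pause sites, ...).
#' @return A list of class `ribo_sim`: `genes`, `truth`, `profiles`,
#'   `abundance`.
#' @export
simulate_ribo_dataset <- function(n_genes = 200L, mean_len = 300,
                                  depth = 20, seed = 1L, ...) {
  genes <- simulate_genome(n_genes, mean_len = mean_len,
                           seed = derive_seed(seed, "genome"))
  truth <- simulate_truth(genes, seed = derive_seed(seed, "truth"), ...)
  profiles <- simulate_footprints(truth, depth = depth,
                                  seed = derive_seed(seed, "counts"))
  structure(list(genes = genes, truth = truth, profiles = profiles,
                 abundance = truth$abundance, seed = seed),
            class = "ribo_sim")
}

#' Simulate a TE dataset with a planted Kozak effect
#'
#' Log translation efficiency is a linear function of gene features plus a
#' planted motif effect and Gaussian noise:
#' \deqn{\log TE = f_m \beta + effect \cdot f^k(context; x_{planted}) + \epsilon}
#' Contexts are uniform random 12-mers around ATG. The planted motif is
#' supplied in the canonical favourable-positive orientation and negated
#' inside \eqn{f^k} so that consensus-matching contexts have \eqn{f^k}
#' near 1 and gain `effect_size` in log TE.
#'
#' @param n_genes Number of genes (default 800).
#' @param planted_x Numeric vector of 36 motif weights, favourable-positive
#'   (e.g. [consensus_weights()]); default plants `"AATAAAATGTCC"` at
#'   strength 2.
#' @param effect_size Motif effect on log TE (default 2).
#' @param beta Coefficients for the linear features (default
#'   `c(1, -0.5, 0.25)`, defining 3 features).
#' @param noise_sd Gaussian noise sd on log TE (default 0.5).
#' @param seed Integer seed.
#' @return A list of class `te_sim`: `features` (gene_id + feat1..featP),
#'   `contexts` (gene_id, context), `te` (gene_id, te), `truth` (planted_x
#'   in generator orientation, effect_size, beta, fk).
#' @export
simulate_te_dataset <- function(n_genes = 800L, planted_x = NULL,
                                effect_size = 2, beta = c(1, -0.5, 0.25),
                                noise_sd = 0.5, seed = 1L) {
  stopifnot(effect_size >= 0)
  if (is.null(planted_x)) {
    planted_x <- consensus_weights("AATAAAATGTCC", strength = 2)
  }
  stopifnot(length(planted_x) == 36)
  withr::with_seed(seed, {
    ids <- sprintf("g%04d", seq_len(n_genes))
    bases <- c("A", "C", "G", "T")
    up <- purrr::map_chr(seq_len(n_genes),
                         ~ paste(sample(bases, 6, replace = TRUE), collapse = ""))
    down <- purrr::map_chr(seq_len(n_genes),
                           ~ paste(sample(bases, 3, replace = TRUE), collapse = ""))
    contexts <- paste0(up, "ATG", down)
    p <- length(beta)
    X <- matrix(stats::rnorm(n_genes * p), n_genes, p)
    colnames(X) <- paste0("feat", seq_len(p))
    # generator orientation: favourable contexts -> x.g negative -> fk ~ 1
    fk <- kozak_feature(contexts, -planted_x)
    log_te <- as.numeric(X %*% beta) + effect_size * fk +
      stats::rnorm(n_genes, 0, noise_sd)
    structure(list(
      features = dplyr::bind_cols(tibble::tibble(gene_id = ids),
                                  tibble::as_tibble(X)),
      contexts = tibble::tibble(gene_id = ids, context = contexts),
      te = tibble::tibble(gene_id = ids, te = exp(log_te)),
      truth = list(planted_x = planted_x, effect_size = effect_size,
                   beta = beta, fk = fk, noise_sd = noise_sd)
    ), class = "te_sim")
  })
}

#' Simulate raw DMS count tracks
#'
#' A and C nucleotides receive Poisson counts proportional to their
#' accessibility times `depth`; G and T positions receive a low Poisson
#' background. Accessibility is a function of position relative to the
#' start codon (so structure features can be planted at known locations).
#'
#' @param genes Gene tibble (sequence = utr5 + cds + utr3).
#' @param accessibility Function mapping a vector of positions relative to
#'   the start codon to accessibilities in `[0, 1]`; default constant 0.8.
#' @param depth Mean count at full accessibility (default 50).
#' @param background Rate multiplier for G/T positions (default 0.05).
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `position` (0-based nt within the gene
#'   sequence), `count`.
#' @export
simulate_dms_counts <- function(genes, accessibility = NULL, depth = 50,
                                background = 0.05, seed = 1L) {
  if (is.null(accessibility)) accessibility <- function(pos) rep(0.8, length(pos))
  seqs <- gene_sequence(genes)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
      n <- nchar(seqs$seq[i])
      bases <- strsplit(seqs$seq[i], "")[[1]]
      rel <- seq_len(n) - 1L - seqs$utr5_len[i]
      acc <- pmin(pmax(accessibility(rel), 0), 1)
      lambda <- ifelse(bases %in% c("A", "C"), depth * acc,
                       depth * background)
      tibble::tibble(gene_id = seqs$gene_id[i], position = seq_len(n) - 1L,
                     count = stats::rpois(n, lambda))
    })
  })
}
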