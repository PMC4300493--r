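# Small handcrafted fixtures shared across tests. Everything is built in
# code; no files.

# Two short genes with fully known codon content (stop codon terminal).
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB"),
    cds = c(
      paste0("ATG", "AAA", "CCC", "AAA", "GGG", "TTT", "CCC", "AAA", "TAA"),
      paste0("ATG", "GGG", "TTT", "GGG", "CCC", "AAA", "TTT", "GGG", "TGA")
    )
  )
}

# Long-format profile table from a named list gene_id -> count vector.
make_profiles <- function(genes, counts) {
  ct <- riboflow:::codon_table(genes)
  ct$count <- unlist(counts[unique(ct$gene_id)], use.names = FALSE)
  ct
}

# Hand-build a ribo_transform for arithmetic tests where dprime/dscaled are
# chosen directly rather than derived from counts.
manual_transform <- function(gene_id, position, codon, dprime,
                             dscaled = dprime, restricted = TRUE) {
  n <- length(dprime)
  data <- tibble::tibble(
    gene_id = rep_len(gene_id, n),
    position = position,
    codon = rep_len(codon, n),
    count = dscaled - 1,
    D = 1, L = n,
    restricted = rep_len(restricted, n),
    dprime = dprime,
    dscaled = dscaled
  )
  gm <- data |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(D = 1, L = dplyr::n(), .groups = "drop")
  structure(list(data = data, scale = 1, gene_means = gm),
            class = "ribo_transform")
}

# Independent brute-force minimiser of the single-codon objective, written
# directly from the model definition (not via the package solver): given
# log-counts y grouped by gene, weights w and penalty C, numerically
# minimise sum_m sum_k (y_mk - beta_m)^2 + C sum_m w_m (beta_m - b)^2.
brute_force_codon <- function(y_by_gene, w, C) {
  M <- length(y_by_gene)
  f <- function(par) {
    beta <- par[1:M]; b <- par[M + 1]
    sum(purrr::map2_dbl(y_by_gene, beta, ~ sum((.x - .y)^2))) +
      C * sum(w * (beta - b)^2)
  }
  init <- c(purrr::map_dbl(y_by_gene, mean), mean(unlist(y_by_gene)))
  best <- NULL
  for (jitter in c(0, -0.5, 0.5)) {
    res <- stats::optim(init + jitter, f, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || res$value < best$value) best <- res
  }
  list(beta = best$par[1:M], b = best$par[M + 1], value = best$value)
}
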