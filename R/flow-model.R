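#' Restricted codon positions used for model training
#'
#' Training ignores the first 100 codons of each gene (or the first 25% for
#' genes shorter than 100 codons), since flow conservation may not hold near
#' the start; the stop codon is never included. Genes whose restricted set is
#' empty (e.g. exactly 100 codons) are unusable for training and receive
#' dwell times from the global parameters only.
#'
#' @param L Gene length in codons (excluding the stop codon).
#' @return Integer vector of 0-based codon positions (possibly empty).
#' @export
#' @examples
#' range(restricted_positions(200))  # 100 199
#' restricted_positions(80)[1]       # 20
restricted_positions <- function(L) {
  stopifnot(L >= 1)
  start <- if (L >= 100) 100L else as.integer(ceiling(0.25 * L))
  if (start > L - 1L) return(integer(0))
  seq.int(start, L - 1L)
}

#' Transform footprint counts for model fitting
#'
#' Adds a pseudo-count of 1 to every footprint count, flow-normalises by the
#' per-gene mean raw count D_m (the initial fixed flux), and scales all
#' values by a single global factor so the smallest transformed count is
#' exactly 1. Two arrays are produced: `dprime` (flow-normalised, the
#' training axis) and `dscaled` (pseudo-counted and globally scaled but not
#' flow-normalised — the count axis on which final fluxes and outlier
#' expectations live).
#'
#' @param profiles Tibble `gene_id`, `position`, `codon`, `count` from
#'   [prepare_profiles()] (or a simulation).
#' @param J_fixed Optional named vector gene_id -> flux to normalise by;
#'   defaults to D_m, the mean raw count per gene.
#' @return A list of class `ribo_transform`: `data` (profiles plus `dprime`,
#'   `dscaled`, `restricted`), `scale`, `gene_means` (gene_id, D, L).
#' @export
transform_counts <- function(profiles, J_fixed = NULL) {
  gm <- profiles %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(D = mean(.data$count), L = dplyr::n(), .groups = "drop")
  if (is.null(J_fixed)) {
    J_fixed <- stats::setNames(gm$D, gm$gene_id)
  }
  if (any(J_fixed[gm$gene_id] <= 0) || any(!is.finite(J_fixed[gm$gene_id]))) {
    stop("J_fixed must be strictly positive for all genes ",
         "(filter genes with zero coverage first)", call. = FALSE)
  }
  data <- profiles %>%
    dplyr::left_join(gm, by = "gene_id") %>%
    dplyr::mutate(
      flownorm = (.data$count + 1) / unname(J_fixed[.data$gene_id]),
      restricted = .data$position >= ifelse(.data$L >= 100, 100,
                                            ceiling(0.25 * .data$L))
    )
  scale <- 1 / min(data$flownorm)
  data <- data %>%
    dplyr::mutate(
      dprime = .data$flownorm * scale,
      dscaled = (.data$count + 1) * scale
    ) %>%
    dplyr::select(-"flownorm")
  if (any(!is.finite(data$dprime))) stop("non-finite transformed counts", call. = FALSE)
  structure(list(data = data, scale = scale, gene_means = gm),
            class = "ribo_transform")
}

#' Baseline per-codon dwell times
#'
#' The simple aggregation estimator: the dwell time of codon c is the mean,
#' over restricted positions carrying c, of the pseudo-counted footprint
#' count normalised by the gene mean D_m. Rate is the reciprocal of dwell.
#'
#' @param profiles Tibble `gene_id`, `position`, `codon`, `count`.
#' @return Tibble `codon`, `dwell`, `rate`, `n` (positions used). Codons
#'   absent from every restricted region are absent from the output.
#' @export
baseline_dwells <- function(profiles) {
  gm <- profiles %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(D = mean(.data$count), L = dplyr::n(), .groups = "drop")
  profiles %>%
    dplyr::left_join(gm, by = "gene_id") %>%
    dplyr::filter(.data$position >= ifelse(.data$L >= 100, 100,
                                           ceiling(0.25 * .data$L))) %>%
    dplyr::group_by(.data$codon) %>%
    dplyr::summarise(dwell = mean((.data$count + 1) / .data$D),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(rate = 1 / .data$dwell) %>%
    dplyr::select("codon", "dwell", "rate", "n")
}

# Global dwell for each codon, imputing the geometric-mean dwell for
# codons that never occur in any restricted region (possible in tiny or
# unusual datasets): such codons have no estimate of their own, so they
# are treated as average.
global_dwell_lookup <- function(fit, codons) {
  mu <- fit$dwell_global$mu[match(codons, fit$dwell_global$codon)]
  if (anyNA(mu)) {
    mu[is.na(mu)] <- exp(mean(log(fit$dwell_global$mu)))
  }
  mu
}

# Internal representation used by the solver: restricted positions only,
# with integer codes for gene and codon.
solver_data <- function(tc) {
  d <- tc$data[tc$data$restricted, , drop = FALSE]
  if (nrow(d) == 0) stop("no gene has a nonempty restricted region", call. = FALSE)
  d$y <- log(d$dprime)
  # soft-constraint weights w_m^c: codon count in gene / codon count overall
  d <- d %>%
    dplyr::group_by(.data$codon) %>%
    dplyr::mutate(N_c = dplyr::n()) %>%
    dplyr::group_by(.data$codon, .data$gene_id) %>%
    dplyr::mutate(n_mc = dplyr::n()) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(w = .data$n_mc / .data$N_c)
  d
}

#' Objective value of the flow model
#'
#' Under the default log-Gaussian loss, the objective is the squared
#' log-space residual between transformed counts and per-gene codon dwells,
#' over restricted positions, plus C times the weighted squared log deviation
#' of per-gene dwells from the global codon dwells (weights w_m^c = codon
#' occurrences in the gene / occurrences overall):
#' \deqn{\sum_m \sum_{k'} (\log d'_{mk} - \log \mu_m^{c(m,k)})^2 +
#'       C \sum_c \sum_m w_m^c (\log \mu_m^c - \log \mu^c)^2}
#' Under the Poisson quasi-likelihood alternative the data term is
#' \eqn{\sum (\mu_m^c - d'_{mk} \log \mu_m^c)}.
#'
#' @param mu_gene Tibble `gene_id`, `codon`, `mu` of per-gene dwell times.
#' @param mu_global Tibble `codon`, `mu` of global dwell times.
#' @param tc A `ribo_transform` object.
#' @param C Soft-constraint weight (default 100).
#' @param loss `"log_gaussian"` (default) or `"poisson"`.
#' @return The scalar objective value.
#' @export
objective_value <- function(mu_gene, mu_global, tc, C = 100,
                            loss = c("log_gaussian", "poisson")) {
  loss <- match.arg(loss)
  if (any(mu_gene$mu <= 0) || any(mu_global$mu <= 0)) {
    stop("dwell times must be strictly positive", call. = FALSE)
  }
  d <- solver_data(tc) %>%
    dplyr::left_join(dplyr::rename(mu_gene, mu_m = "mu"),
                     by = c("gene_id", "codon"))
  if (any(is.na(d$mu_m))) {
    stop("mu_gene missing for some (gene, codon) in the restricted region",
         call. = FALSE)
  }
  data_term <- if (loss == "log_gaussian") {
    sum((d$y - log(d$mu_m))^2)
  } else {
    sum(d$mu_m - d$dprime * log(d$mu_m))
  }
  pen <- d %>%
    dplyr::distinct(.data$gene_id, .data$codon, .data$mu_m, .data$w) %>%
    dplyr::left_join(dplyr::rename(mu_global, mu_c = "mu"), by = "codon")
  penalty <- sum(pen$w * (log(pen$mu_m) - log(pen$mu_c))^2)
  data_term + C * penalty
}

# Closed-form minimiser of the log-Gaussian objective restricted to one
# codon: per-gene log-dwells beta_m and global log-dwell b satisfy
#   beta_m = (S_m + C w_m b) / (n_m + C w_m),  b = sum(w beta) / sum(w),
# which solves to a single linear equation in b.
solve_codon_closed_form <- function(S, n, w, C) {
  if (C == 0) {
    beta <- S / n
    b <- sum(w * beta) / sum(w)
    return(list(beta = beta, b = b))
  }
  denom <- n + C * w
  b <- sum(w * S / denom) / sum(w * n / denom)
  beta <- (S + C * w * b) / denom
  list(beta = beta, b = b)
}

# Poisson-loss subproblem, solved numerically in log space.
solve_codon_poisson <- function(y_by_gene, dprime_by_gene, w, C, beta0, b0,
                                lbfgs = list(max_iter = 5000, grad_tol = 1e-5)) {
  M <- length(w)
  fn <- function(par) {
    beta <- par[1:M]; b <- par[M + 1]
    dt <- sum(purrr::map2_dbl(seq_len(M), beta, function(m, bm) {
      sum(exp(bm) - dprime_by_gene[[m]] * bm)
    }))
    dt + C * sum(w * (beta - b)^2)
  }
  gr <- function(par) {
    beta <- par[1:M]; b <- par[M + 1]
    gb <- purrr::map2_dbl(seq_len(M), beta, function(m, bm) {
      nm <- length(dprime_by_gene[[m]])
      nm * exp(bm) - sum(dprime_by_gene[[m]])
    }) + 2 * C * w * (beta - b)
    c(gb, -2 * C * sum(w * (beta - b)))
  }
  res <- stats::optim(c(beta0, b0), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = lbfgs$max_iter,
                                     pgtol = lbfgs$grad_tol))
  list(beta = res$par[1:M], b = res$par[M + 1], convergence = res$convergence)
}

#' Solve the per-codon subproblem
#'
#' Minimises the flow-model objective over the dwell parameters of a single
#' codon (all other codons fixed; the blocks are independent given fixed
#' fluxes). Under the log-Gaussian loss the exact closed form is used; under
#' the Poisson loss an L-BFGS solve in log space.
#'
#' @param codon A codon string, e.g. `"AAA"`.
#' @param tc A `ribo_transform` object.
#' @param C Soft-constraint weight.
#' @param loss `"log_gaussian"` or `"poisson"`.
#' @return List with `mu_gene` (tibble `gene_id`, `mu`), `mu_global`
#'   (scalar), and `weights` (tibble `gene_id`, `w`).
#' @export
solve_codon_subproblem <- function(codon, tc, C = 100,
                                   loss = c("log_gaussian", "poisson")) {
  loss <- match.arg(loss)
  d <- solver_data(tc)
  d <- d[d$codon == codon, , drop = FALSE]
  if (nrow(d) == 0) {
    stop("codon ", codon, " does not occur in any restricted region", call. = FALSE)
  }
  gs <- d %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(S = sum(.data$y), n = dplyr::n(), w = .data$w[1],
                     .groups = "drop")
  if (loss == "log_gaussian") {
    sol <- solve_codon_closed_form(gs$S, gs$n, gs$w, C)
  } else {
    dprime_by_gene <- split(d$dprime, factor(d$gene_id, levels = gs$gene_id))
    sol <- solve_codon_poisson(NULL, dprime_by_gene, gs$w, C,
                               beta0 = gs$S / gs$n,
                               b0 = sum(gs$S) / sum(gs$n))
  }
  list(
    mu_gene = tibble::tibble(gene_id = gs$gene_id, mu = exp(sol$beta)),
    mu_global = exp(sol$b),
    weights = tibble::tibble(gene_id = gs$gene_id, w = gs$w)
  )
}

#' Fit the flow-conservation translation model
#'
#' Estimates per-gene per-codon ribosome dwell times \eqn{\mu_m^c} softly
#' tied to global codon dwell times \eqn{\mu^c}, and per-gene protein
#' synthesis fluxes \eqn{J_m}, from codon-resolution footprint counts.
#'
#' The procedure: (1) fluxes are fixed to the per-gene mean raw count D_m;
#' (2) counts are pseudo-counted, flow-normalised and globally scaled
#' ([transform_counts()]); (3) dwells are initialised from the baseline
#' estimator, shifted in log space so their mean equals the log of the mean
#' transformed count, plus a small seeded perturbation; (4) coordinate
#' descent over codons (lexicographic order) minimises the objective until
#' the parameter change is below `weight_tol` or the objective change below
#' `fun_tol`; (5) final fluxes are recomputed from the fitted dwells with
#' [compute_flows()]. Stop codons never receive parameters. Deterministic
#' given `seed`.
#'
#' @param profiles Tibble `gene_id`, `position`, `codon`, `count`.
#' @param C Soft-constraint weight tying per-gene dwells to global dwells
#'   (default 100).
#' @param mode `"per_gene_codon"` (default; one dwell per codon per gene),
#'   `"per_position"` (one dwell per position, tied to global codon dwells),
#'   or `"global_only"` (global codon dwells only, no soft constraint).
#' @param loss `"log_gaussian"` (default) or `"poisson"`.
#' @param seed Integer seed for the initialisation perturbation.
#' @param max_sweeps Maximum coordinate-descent sweeps.
#' @param weight_tol,fun_tol Coordinate-descent stopping tolerances on the
#'   maximum absolute log-dwell change and on the objective change.
#' @param init_jitter Half-width of the uniform log-space perturbation at
#'   initialisation.
#' @return An object of class `flow_fit`: tibbles `dwell_global` (codon,
#'   mu), `dwell_gene` (gene_id, codon, mu, weight), `dwell_position`
#'   (per_position mode only), `flows` (gene_id, J), the objective `trace`,
#'   the `transform`, and the configuration.
#' @export
fit_flow_model <- function(profiles, C = 100,
                           mode = c("per_gene_codon", "per_position", "global_only"),
                           loss = c("log_gaussian", "poisson"),
                           seed = 1L, max_sweeps = 50L,
                           weight_tol = 5e-5, fun_tol = 1e-5,
                           init_jitter = 0.01) {
  mode <- match.arg(mode)
  loss <- match.arg(loss)
  stopifnot(C >= 0, weight_tol > 0, fun_tol > 0)
  tc <- transform_counts(profiles)
  d <- solver_data(tc)
  if (mode == "per_position") {
    return(fit_per_position(profiles, tc, d, C, seed, max_sweeps,
                            weight_tol, fun_tol, init_jitter))
  }

  codons <- sort(unique(d$codon))
  target_mean <- log(mean(d$dprime))  # the dataset's analogue of log(7.2)

  base <- baseline_dwells(profiles)
  beta_init <- log(base$dwell[match(codons, base$codon)])
  beta_init <- beta_init - mean(beta_init) + target_mean
  beta_init <- withr::with_seed(seed, {
    beta_init + stats::runif(length(beta_init), -init_jitter, init_jitter)
  })
  names(beta_init) <- codons

  # per-gene structures, grouped by codon
  gs <- d %>%
    dplyr::group_by(.data$codon, .data$gene_id) %>%
    dplyr::summarise(S = sum(.data$y), n = dplyr::n(), w = .data$w[1],
                     .groups = "drop")
  gs_by_codon <- split(gs, gs$codon)
  dprime_by_codon <- if (loss == "poisson") {
    split(d[, c("gene_id", "dprime")], d$codon)
  } else NULL

  # state: per codon, vector beta_m and scalar b
  state <- purrr::map(codons, function(cod) {
    g <- gs_by_codon[[cod]]
    list(beta = stats::setNames(rep(beta_init[[cod]], nrow(g)), g$gene_id),
         b = beta_init[[cod]])
  })
  names(state) <- codons

  objective_from_state <- function(state) {
    total <- 0
    for (cod in codons) {
      g <- gs_by_codon[[cod]]
      beta <- state[[cod]]$beta; b <- state[[cod]]$b
      if (loss == "log_gaussian") {
        # sum over positions of (y - beta_m)^2 decomposes via S, n and sum(y^2)
        yy <- d$y[d$codon == cod]
        bm <- beta[match(d$gene_id[d$codon == cod], g$gene_id)]
        total <- total + sum((yy - bm)^2)
      } else {
        dp <- dprime_by_codon[[cod]]
        bm <- beta[match(dp$gene_id, g$gene_id)]
        total <- total + sum(exp(bm) - dp$dprime * bm)
      }
      if (mode == "per_gene_codon") {
        total <- total + C * sum(g$w * (beta - b)^2)
      }
    }
    total
  }

  trace <- objective_from_state(state)
  for (sweep in seq_len(max_sweeps)) {
    max_delta <- 0
    for (cod in codons) {
      g <- gs_by_codon[[cod]]
      if (mode == "global_only") {
        b_new <- sum(g$S) / sum(g$n)
        sol <- list(beta = rep(b_new, nrow(g)), b = b_new)
      } else if (loss == "log_gaussian") {
        sol <- solve_codon_closed_form(g$S, g$n, g$w, C)
      } else {
        dp <- dprime_by_codon[[cod]]
        sol <- solve_codon_poisson(
          NULL, split(dp$dprime, factor(dp$gene_id, levels = g$gene_id)),
          g$w, C, beta0 = unname(state[[cod]]$beta), b0 = state[[cod]]$b)
      }
      max_delta <- max(max_delta,
                       abs(sol$beta - unname(state[[cod]]$beta)),
                       abs(sol$b - state[[cod]]$b))
      state[[cod]] <- list(beta = stats::setNames(sol$beta, g$gene_id),
                           b = sol$b)
    }
    trace <- c(trace, objective_from_state(state))
    if (max_delta < weight_tol) break
    if (abs(trace[length(trace)] - trace[length(trace) - 1]) < fun_tol) break
  }

  dwell_gene <- purrr::map_dfr(codons, function(cod) {
    g <- gs_by_codon[[cod]]
    tibble::tibble(gene_id = g$gene_id, codon = cod,
                   mu = exp(unname(state[[cod]]$beta)), weight = g$w)
  }) %>% dplyr::arrange(.data$gene_id, .data$codon)
  dwell_global <- tibble::tibble(
    codon = codons,
    mu = purrr::map_dbl(codons, ~ exp(state[[.x]]$b))
  )

  fit <- structure(list(
    dwell_global = dwell_global,
    dwell_gene = dwell_gene,
    dwell_position = NULL,
    flows = NULL,
    trace = trace,
    transform = tc,
    config = list(C = C, mode = mode, loss = loss, seed = seed,
                  weight_tol = weight_tol, fun_tol = fun_tol,
                  target_mean_log_dwell = target_mean,
                  n_sweeps = length(trace) - 1L)
  ), class = "flow_fit")
  fit$flows <- compute_flows(fit)
  fit
}

# Per-position model variant: an individual dwell per (m, k), softly tied to
# the global codon dwell with weight 1/N_c per position.
fit_per_position <- function(profiles, tc, d, C, seed, max_sweeps,
                             weight_tol, fun_tol, init_jitter) {
  target_mean <- log(mean(d$dprime))
  nz_mean <- mean(d$count[d$count > 0])
  if (!is.finite(nz_mean)) nz_mean <- 1
  init_raw <- ifelse(d$count > 0, d$count, nz_mean) /
    d$D
  beta0 <- log(init_raw)
  beta0 <- beta0 - mean(beta0) + target_mean
  base <- baseline_dwells(profiles)
  codons <- sort(unique(d$codon))
  b0 <- log(base$dwell[match(codons, base$codon)])
  b0 <- b0 - mean(b0) + target_mean
  withr::with_seed(seed, {
    beta0 <- beta0 + stats::runif(length(beta0), -init_jitter, init_jitter)
    b0 <- b0 + stats::runif(length(b0), -init_jitter, init_jitter)
  })
  names(b0) <- codons
  d$w_pos <- 1 / d$N_c

  obj <- function(beta, b) {
    sum((d$y - beta)^2) + C * sum(d$w_pos * (beta - b[d$codon])^2)
  }
  beta <- beta0; b <- b0
  trace <- obj(beta, b)
  for (sweep in seq_len(max_sweeps)) {
    beta_new <- (d$y + C * d$w_pos * b[d$codon]) / (1 + C * d$w_pos)
    b_new <- tapply(d$w_pos * beta_new, d$codon, sum) /
      tapply(d$w_pos, d$codon, sum)
    b_new <- stats::setNames(as.numeric(b_new[codons]), codons)
    max_delta <- max(abs(beta_new - beta), abs(b_new - b))
    beta <- beta_new; b <- b_new
    trace <- c(trace, obj(beta, b))
    if (max_delta < weight_tol) break
    if (abs(trace[length(trace)] - trace[length(trace) - 1]) < fun_tol) break
  }
  dwell_position <- tibble::tibble(
    gene_id = d$gene_id, position = d$position, codon = d$codon,
    mu = exp(beta)
  )
  fit <- structure(list(
    dwell_global = tibble::tibble(codon = codons, mu = exp(unname(b))),
    dwell_gene = NULL,
    dwell_position = dwell_position,
    flows = NULL,
    trace = trace,
    transform = tc,
    config = list(C = C, mode = "per_position", loss = "log_gaussian",
                  seed = seed, weight_tol = weight_tol, fun_tol = fun_tol,
                  target_mean_log_dwell = target_mean,
                  n_sweeps = length(trace) - 1L)
  ), class = "flow_fit")
  fit$flows <- compute_flows(fit)
  fit
}

#' Compute protein synthesis fluxes from a fitted model
#'
#' The flux of gene m is the mean, over the full gene body, of the
#' dwell-corrected counts: \eqn{J_m = \sum_k (d_{mk}/\mu_{mk}) / L_m}, where
#' counts carry the pseudo-count and the single global scale factor (but are
#' not flow-normalised), and \eqn{\mu_{mk}} is the per-gene codon dwell,
#' falling back to the global codon dwell where no per-gene parameter exists
#' (positions outside the restricted region, or genes excluded from
#' training).
#'
#' @param fit A `flow_fit` object.
#' @param tc Optional `ribo_transform` (defaults to the one inside `fit`).
#' @return Tibble `gene_id`, `J`.
#' @export
compute_flows <- function(fit, tc = NULL) {
  if (is.null(tc)) tc <- fit$transform
  d <- tc$data
  mu <- global_dwell_lookup(fit, d$codon)
  if (!is.null(fit$dwell_position)) {
    key <- paste(d$gene_id, d$position)
    pk <- paste(fit$dwell_position$gene_id, fit$dwell_position$position)
    idx <- match(key, pk)
    mu <- ifelse(is.na(idx), mu, fit$dwell_position$mu[idx])
  } else if (!is.null(fit$dwell_gene)) {
    key <- paste(d$gene_id, d$codon)
    gk <- paste(fit$dwell_gene$gene_id, fit$dwell_gene$codon)
    idx <- match(key, gk)
    mu <- ifelse(is.na(idx), mu, fit$dwell_gene$mu[idx])
  }
  if (any(is.na(mu))) {
    stop("no dwell available for some codons; was the model fitted?", call. = FALSE)
  }
  tibble::tibble(gene_id = d$gene_id, jk = d$dscaled / mu) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(J = mean(.data$jk), .groups = "drop")
}

#' Normalised codon translation rates
#'
#' Rates are the reciprocal of the global codon dwell times, normalised by
#' the minimum rate so the slowest codon has rate 1.
#'
#' @param fit A `flow_fit` object (or a tibble `codon`, `mu`).
#' @return Tibble `codon`, `rate` (min rate = 1).
#' @export
codon_rates <- function(fit) {
  tab <- if (inherits(fit, "flow_fit")) fit$dwell_global else fit
  rate <- 1 / tab$mu
  tibble::tibble(codon = tab$codon, rate = rate / min(rate))
}

#' @export
print.flow_fit <- function(x, ...) {
  cat("<flow_fit> ", x$config$mode, "/", x$config$loss,
      ", C = ", x$config$C, "\n", sep = "")
  cat("  genes: ", nrow(x$flows),
      "; codons: ", nrow(x$dwell_global),
      "; sweeps: ", x$config$n_sweeps, "\n", sep = "")
  cat("  objective: ", format(utils::tail(x$trace, 1)), "\n", sep = "")
  invisible(x)
}
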