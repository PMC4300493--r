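# Kozak context handling -----------------------------------------------------
#
# A Kozak context is the 12-mer spanning positions -6..+6 around the start
# codon: characters 1-6 are positions -6..-1, characters 7-9 are ATG, and
# characters 10-12 are positions +4..+6. The start codon itself carries no
# free parameters, leaving 9 positions x 4 bases = 36 indicator weights.

KOZAK_POSITIONS <- c(-6:-1, 4:6)
KOZAK_BASES <- c("A", "C", "G", "T")

check_context <- function(context) {
  context <- normalize_nt(context)
  if (any(nchar(context) != 12)) {
    stop("Kozak contexts must be 12 nt (-6..+6 around the start)", call. = FALSE)
  }
  if (any(substr(context, 7, 9) != "ATG")) {
    stop("Kozak context must contain ATG at positions 7-9", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", context))) {
    stop("ambiguous base in Kozak context", call. = FALSE)
  }
  context
}

# One-hot encode contexts into an n x 36 indicator matrix g.
kozak_onehot <- function(contexts) {
  contexts <- check_context(contexts)
  keep <- c(1:6, 10:12)
  n <- length(contexts)
  G <- matrix(0, n, 36)
  for (j in seq_along(keep)) {
    base <- substr(contexts, keep[j], keep[j])
    idx <- match(base, KOZAK_BASES)
    G[cbind(seq_len(n), (j - 1L) * 4L + idx)] <- 1
  }
  colnames(G) <- paste0("p", rep(KOZAK_POSITIONS, each = 4), "_",
                        rep(KOZAK_BASES, times = 9))
  G
}

#' Sigmoid Kozak feature
#'
#' The learnable start-context feature \eqn{f^k = 1/(1 + \exp(x \cdot g))},
#' where g is the 36-indicator one-hot encoding of the 9 non-AUG positions
#' of the context and x the corresponding weights. More negative
#' \eqn{x \cdot g} pushes \eqn{f^k} toward 1; the sign convention is
#' absorbed by the regression weight on the feature.
#'
#' @param contexts Character vector of 12-nt contexts (ATG at positions
#'   7–9).
#' @param x Numeric vector of 36 weights.
#' @return Numeric vector in (0, 1).
#' @export
#' @examples
#' kozak_feature("AAAAAAATGCCC", rep(0, 36))  # 0.5
kozak_feature <- function(contexts, x) {
  stopifnot(length(x) == 36)
  G <- kozak_onehot(contexts)
  as.numeric(1 / (1 + exp(G %*% x)))
}

#' Kozak similarity as KL divergence to a PWM
#'
#' Scores a context against a position weight matrix by the Kullback–Leibler
#' divergence of the context (a point mass at each position) from the PWM
#' columns: the sum over the 9 non-AUG positions of \eqn{-\log p} for the
#' observed base. Zero means a perfect match to a degenerate PWM; lower is
#' closer.
#'
#' @param contexts Character vector of 12-nt contexts.
#' @param pwm 9 x 4 matrix of base probabilities (rows = positions -6..-1,
#'   +4..+6; columns = A, C, G, T).
#' @return Numeric vector of divergence scores (Inf if a base has
#'   probability 0).
#' @export
kozak_similarity <- function(contexts, pwm) {
  stopifnot(nrow(pwm) == 9, ncol(pwm) == 4)
  contexts <- check_context(contexts)
  keep <- c(1:6, 10:12)
  score <- numeric(length(contexts))
  for (j in seq_along(keep)) {
    base <- substr(contexts, keep[j], keep[j])
    p <- pwm[j, match(base, KOZAK_BASES)]
    score <- score - log(p)
  }
  score
}

#' Convert motif weights to a position weight matrix
#'
#' At each of the 9 positions the four weights are shifted so the most
#' negative is 0 and normalised by their sum; all-equal weights give a
#' uniform 0.25 row.
#'
#' @param x Numeric vector of 36 weights (canonical orientation: larger =
#'   more favourable).
#' @return 9 x 4 matrix, rows named by position, columns A, C, G, T; rows
#'   sum to 1.
#' @export
motif_to_pwm <- function(x) {
  stopifnot(length(x) == 36)
  pwm <- matrix(NA_real_, 9, 4,
                dimnames = list(as.character(KOZAK_POSITIONS), KOZAK_BASES))
  for (p in 1:9) {
    w <- x[(p - 1) * 4 + 1:4]
    w <- w - min(w)
    pwm[p, ] <- if (sum(w) == 0) rep(0.25, 4) else w / sum(w)
  }
  pwm
}

#' Indicator weights for a fixed consensus motif
#'
#' Builds a 36-weight vector from a 12-nt IUPAC consensus (e.g. the yeast
#' Kozak consensus `"WAMAMAATGTCY"`): bases allowed at a position receive
#' `+strength`, others `-strength` (favourable-positive, the canonical
#' orientation used by [motif_to_pwm()]).
#'
#' @param consensus 12-character IUPAC string with ATG at positions 7–9.
#' @param strength Weight magnitude (default 1).
#' @return Numeric vector of 36 weights.
#' @export
consensus_weights <- function(consensus, strength = 1) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  stopifnot(nchar(consensus) == 12)
  keep <- c(1:6, 10:12)
  x <- numeric(36)
  for (j in seq_along(keep)) {
    ch <- toupper(substr(consensus, keep[j], keep[j]))
    allowed <- iupac[[ch]]
    if (is.null(allowed)) stop("unknown IUPAC code: ", ch, call. = FALSE)
    x[(j - 1) * 4 + 1:4] <- ifelse(KOZAK_BASES %in% allowed,
                                   strength, -strength)
  }
  x
}

# Elastic net by coordinate descent ------------------------------------------
# minimise sum((y - b0 - X w)^2) + lambda1 * sum|w| + lambda2 * sum(w^2)
# with an unpenalised intercept. Small p; plain CD suffices.
elastic_net_cd <- function(X, y, lambda1, lambda2, max_iter = 500,
                           tol = 1e-9, w_init = NULL) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  p <- ncol(X)
  w <- if (is.null(w_init)) rep(0, p) else w_init
  xtx <- colSums(Xc^2)
  r <- yc - Xc %*% w
  for (it in seq_len(max_iter)) {
    w_old <- w
    for (j in seq_len(p)) {
      rho <- sum(Xc[, j] * r) + xtx[j] * w[j]
      wj <- sign(rho) * max(abs(rho) - lambda1 / 2, 0) / (xtx[j] + lambda2)
      if (wj != w[j]) {
        r <- r - Xc[, j] * (wj - w[j])
        w[j] <- wj
      }
    }
    if (max(abs(w - w_old)) < tol) break
  }
  b0 <- ym - sum(xm * w)
  list(w = w, intercept = b0)
}

# Alternating fit of (w, x): elastic net for w given the Kozak feature, then
# BFGS on the smooth objective for x given w. X_fixed excludes the Kozak
# column; G is the one-hot matrix.
alternating_fit <- function(X_fixed, G, y, lambda1, lambda2,
                            max_alt = 100, tol = 1e-5, x_init = NULL,
                            seed = 1L, bfgs_maxit = 50) {
  n <- length(y)
  x <- if (is.null(x_init)) {
    withr::with_seed(seed, stats::runif(36, -0.1, 0.1))
  } else x_init
  w <- NULL
  obj_prev <- Inf
  for (alt in seq_len(max_alt)) {
    fk <- as.numeric(1 / (1 + exp(G %*% x)))
    X <- cbind(X_fixed, kozak = fk)
    en <- elastic_net_cd(X, y, lambda1, lambda2, w_init = w)
    w <- en$w
    b0 <- en$intercept
    wk <- w[length(w)]
    # x-step: RSS + lambda2 ||x||^2, smooth in x
    pred_fixed <- b0 + as.numeric(X_fixed %*% w[-length(w)])
    fn <- function(xv) {
      f <- as.numeric(1 / (1 + exp(G %*% xv)))
      sum((y - pred_fixed - wk * f)^2) + lambda2 * sum(xv^2)
    }
    gr <- function(xv) {
      u <- as.numeric(G %*% xv)
      f <- 1 / (1 + exp(u))
      r <- y - pred_fixed - wk * f
      as.numeric(t(G) %*% (2 * r * wk * f * (1 - f))) + 2 * lambda2 * xv
    }
    if (wk != 0) {
      opt <- stats::optim(x, fn, gr, method = "BFGS",
                          control = list(maxit = bfgs_maxit))
      x <- opt$par
    }
    fk <- as.numeric(1 / (1 + exp(G %*% x)))
    resid <- y - b0 - as.numeric(X_fixed %*% w[-length(w)]) - wk * fk
    obj <- sum(resid^2) + lambda1 * sum(abs(w)) +
      lambda2 * (sum(w^2) + sum(x^2))
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) < tol * max(1, abs(obj_prev))) {
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  list(w = w, intercept = b0, x = x, objective = obj_prev, n_alt = alt)
}

predict_te <- function(X_fixed, G, w, intercept, x) {
  fk <- as.numeric(1 / (1 + exp(G %*% x)))
  intercept + as.numeric(cbind(X_fixed, fk) %*% w)
}

# Canonicalise the sign ambiguity: (x, w_k) and (-x, -w_k) with an intercept
# shift fit identically (f -> 1 - f). Convention: w_k <= 0, so favourable
# bases carry the most positive weights.
canonicalize_kozak <- function(w, intercept, x) {
  wk <- w[length(w)]
  if (wk > 0) {
    intercept <- intercept + wk
    w[length(w)] <- -wk
    x <- -x
  }
  list(w = w, intercept = intercept, x = x)
}

#' Fit the translation-efficiency regression with a learnable Kozak motif
#'
#' Regresses (log, z-scored) translation efficiency on a set of gene
#' features plus a sigmoid Kozak-context feature, with an L1 (sparsity) and
#' L2 (shrinkage) penalty:
#' \deqn{\sum_m (TE_m - w \cdot f_m)^2 + \lambda_1 \|w\|_1 +
#'       \lambda_2 (\|w\|_2^2 + \|x\|_2^2)}
#' The feature weights w are solved by coordinate descent given the motif
#' weights x; x is then updated by quasi-Newton steps on the smooth part of
#' the objective; the two alternate to convergence. Hyperparameters are
#' chosen by 5-fold cross-validation on the first training split (or every
#' split with `cv_per_split = TRUE`). The procedure repeats over `n_splits`
#' random train/test splits; reported errors are means over splits, the
#' motif is the average of the per-split canonical x.
#'
#' @param features Tibble: `gene_id` plus numeric feature columns (tAI, UTR
#'   energies, CDS length, mRNA abundance, ...). Columns are z-scored
#'   internally.
#' @param te Tibble `gene_id`, `te` (positive; log-transformed and z-scored
#'   internally).
#' @param contexts Tibble `gene_id`, `context` of 12-nt Kozak contexts.
#' @param lambda_grid Candidate values for both penalties (crossed).
#' @param n_splits Number of random train/test splits (default 100).
#' @param test_size Test-set size: the smaller of this and 20% of genes
#'   (default 400).
#' @param n_folds CV folds (default 5).
#' @param seed Integer seed (splits, CV folds, initialisation, null
#'   permutations).
#' @param cv_per_split Re-run hyperparameter CV on every split (slow);
#'   default FALSE reuses the first split's choice.
#' @param max_alt,tol Alternation limit and relative-objective tolerance.
#' @param cv_max_alt Alternation limit inside CV (cheaper).
#' @return An object of class `kozak_fit`: averaged weights `w` (named),
#'   motif `x` (canonical orientation), `pwm`, chosen `lambda1`/`lambda2`,
#'   `cv_grid`, per-split tibble `splits` (test_error, null_error), mean
#'   `test_error` and `null_error`, and bookkeeping needed by
#'   [evaluate_fixed_motif()].
#' @export
fit_te_regression <- function(features, te, contexts,
                              lambda_grid = 10^seq(-3, 1),
                              n_splits = 100L, test_size = 400L,
                              n_folds = 5L, seed = 1L,
                              cv_per_split = FALSE,
                              max_alt = 100L, tol = 1e-5,
                              cv_max_alt = 5L) {
  df <- features %>%
    dplyr::inner_join(te, by = "gene_id") %>%
    dplyr::inner_join(contexts, by = "gene_id")
  n <- nrow(df)
  if (n < 50) stop("too few genes with complete features", call. = FALSE)
  feat_names <- setdiff(names(features), "gene_id")
  X_fixed <- as.matrix(df[, feat_names, drop = FALSE])
  X_fixed <- scale(X_fixed)
  if (any(!is.finite(X_fixed))) {
    stop("constant or missing feature column", call. = FALSE)
  }
  y <- as.numeric(scale(log(df$te)))
  G <- kozak_onehot(df$context)
  ts <- min(as.integer(test_size), floor(0.2 * n))

  splits <- withr::with_seed(derive_seed(seed, "splits"), {
    purrr::map(seq_len(n_splits), ~ sample(n, ts))
  })

  grid <- expand.grid(lambda1 = lambda_grid, lambda2 = lambda_grid)
  run_cv <- function(train_idx, split_i) {
    folds <- withr::with_seed(derive_seed(seed, paste0("folds", split_i)), {
      sample(rep_len(seq_len(n_folds), length(train_idx)))
    })
    errs <- purrr::map_dbl(seq_len(nrow(grid)), function(gi) {
      l1 <- grid$lambda1[gi]; l2 <- grid$lambda2[gi]
      mean(purrr::map_dbl(seq_len(n_folds), function(f) {
        tr <- train_idx[folds != f]; va <- train_idx[folds == f]
        fit <- alternating_fit(X_fixed[tr, , drop = FALSE], G[tr, , drop = FALSE],
                               y[tr], l1, l2, max_alt = cv_max_alt, tol = tol,
                               seed = derive_seed(seed, paste0("init", split_i)))
        mean((y[va] - predict_te(X_fixed[va, , drop = FALSE],
                                 G[va, , drop = FALSE],
                                 fit$w, fit$intercept, fit$x))^2)
      }))
    })
    dplyr::mutate(tibble::as_tibble(grid), cv_error = errs)
  }

  cv_grid <- NULL
  lambda1 <- lambda2 <- NA_real_
  split_rows <- vector("list", n_splits)
  x_mat <- matrix(NA_real_, n_splits, 36)
  w_mat <- matrix(NA_real_, n_splits, length(feat_names) + 1)

  for (s in seq_len(n_splits)) {
    test_idx <- splits[[s]]
    train_idx <- setdiff(seq_len(n), test_idx)
    if (s == 1 || cv_per_split) {
      cvg <- run_cv(train_idx, s)
      best <- cvg[which.min(cvg$cv_error), ]
      lambda1 <- best$lambda1; lambda2 <- best$lambda2
      if (s == 1) cv_grid <- cvg
    }
    fit <- alternating_fit(X_fixed[train_idx, , drop = FALSE],
                           G[train_idx, , drop = FALSE],
                           y[train_idx], lambda1, lambda2,
                           max_alt = max_alt, tol = tol,
                           seed = derive_seed(seed, paste0("init", s)))
    test_err <- mean((y[test_idx] -
                        predict_te(X_fixed[test_idx, , drop = FALSE],
                                   G[test_idx, , drop = FALSE],
                                   fit$w, fit$intercept, fit$x))^2)
    y_perm <- withr::with_seed(derive_seed(seed, paste0("null", s)), {
      replace(y, train_idx, sample(y[train_idx]))
    })
    nfit <- alternating_fit(X_fixed[train_idx, , drop = FALSE],
                            G[train_idx, , drop = FALSE],
                            y_perm[train_idx], lambda1, lambda2,
                            max_alt = max_alt, tol = tol,
                            seed = derive_seed(seed, paste0("init", s)))
    null_err <- mean((y[test_idx] -
                        predict_te(X_fixed[test_idx, , drop = FALSE],
                                   G[test_idx, , drop = FALSE],
                                   nfit$w, nfit$intercept, nfit$x))^2)
    can <- canonicalize_kozak(fit$w, fit$intercept, fit$x)
    x_mat[s, ] <- can$x
    w_mat[s, ] <- can$w
    split_rows[[s]] <- tibble::tibble(split = s, test_error = test_err,
                                      null_error = null_err,
                                      w_kozak = can$w[length(can$w)])
  }

  x_avg <- colMeans(x_mat)
  w_avg <- colMeans(w_mat)
  names(w_avg) <- c(feat_names, "kozak")
  structure(list(
    w = w_avg,
    x = x_avg,
    pwm = motif_to_pwm(x_avg),
    lambda1 = lambda1, lambda2 = lambda2,
    cv_grid = cv_grid,
    splits = dplyr::bind_rows(split_rows),
    test_error = mean(purrr::map_dbl(split_rows, "test_error")),
    null_error = mean(purrr::map_dbl(split_rows, "null_error")),
    feature_names = feat_names,
    config = list(n_splits = n_splits, test_size = ts, n_folds = n_folds,
                  seed = seed, lambda_grid = lambda_grid,
                  max_alt = max_alt, tol = tol, n = n),
    data = list(X_fixed = X_fixed, G = G, y = y, splits = splits)
  ), class = "kozak_fit")
}

#' Test error of a fixed (non-learned) motif
#'
#' Re-runs the TE regression over the same train/test splits with the motif
#' weights frozen at `fixed_x` — rescaled so that the sum of the four
#' weights at each position matches the learned motif's sum at that position
#' — learning only the feature weights w. Comparing the returned error to
#' the learned-motif error measures how much the learned motif explains.
#'
#' @param fit A `kozak_fit` object.
#' @param fixed_x Numeric vector of 36 motif weights (e.g. from
#'   [consensus_weights()]).
#' @return A list: `test_error` (mean over splits), `splits` tibble,
#'   `fixed_x` (after rescaling).
#' @export
evaluate_fixed_motif <- function(fit, fixed_x) {
  stopifnot(inherits(fit, "kozak_fit"), length(fixed_x) == 36)
  x_learn <- fit$x
  x_fix <- fixed_x
  for (p in 1:9) {
    i <- (p - 1) * 4 + 1:4
    s_l <- sum(x_learn[i]); s_f <- sum(x_fix[i])
    if (abs(s_f) > 1e-12) {
      x_fix[i] <- x_fix[i] * (s_l / s_f)
    } else {
      x_fix[i] <- x_fix[i] + (s_l - s_f) / 4
    }
  }
  X_fixed <- fit$data$X_fixed; G <- fit$data$G; y <- fit$data$y
  n <- length(y)
  fk <- as.numeric(1 / (1 + exp(G %*% x_fix)))
  errs <- purrr::map_dbl(seq_along(fit$data$splits), function(s) {
    test_idx <- fit$data$splits[[s]]
    train_idx <- setdiff(seq_len(n), test_idx)
    X <- cbind(X_fixed, kozak = fk)
    en <- elastic_net_cd(X[train_idx, , drop = FALSE], y[train_idx],
                         fit$lambda1, fit$lambda2)
    pred <- en$intercept + as.numeric(X[test_idx, , drop = FALSE] %*% en$w)
    mean((y[test_idx] - pred)^2)
  })
  list(test_error = mean(errs),
       splits = tibble::tibble(split = seq_along(errs), test_error = errs),
       fixed_x = x_fix)
}

#' Export a PWM in MEME minimal motif format
#'
#' @param pwm 9 x 4 PWM from [motif_to_pwm()].
#' @param path Output path.
#' @param name Motif name.
#' @return `path`, invisibly.
#' @export
write_meme_pwm <- function(pwm, path, name = "kozak") {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d", nrow(pwm)),
    apply(pwm, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.kozak_fit <- function(x, ...) {
  cat("<kozak_fit> ", x$config$n_splits, " splits, lambda1 = ", x$lambda1,
      ", lambda2 = ", x$lambda2, "\n", sep = "")
  cat("  test error: ", format(x$test_error, digits = 4),
      " (null: ", format(x$null_error, digits = 4), ")\n", sep = "")
  cons <- apply(x$pwm, 1, function(r) KOZAK_BASES[which.max(r)])
  cat("  motif consensus (-6..-1,+4..+6): ", paste(cons, collapse = ""),
      "\n", sep = "")
  invisible(x)
}
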