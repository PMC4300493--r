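#' Normalise DMS structure-probing counts to reactivities
#'
#' DMS modifies accessible (unpaired) A and C bases; raw per-nucleotide
#' counts are converted to reactivities in `[0, 1]` window by window. Each
#' gene is tiled into consecutive windows of `window` nt (a final partial
#' window stands alone; genes shorter than one window form a single window).
#' Within a window, the "top 5%" of A/C positions are the
#' `ceiling(0.05 * n_AC)` highest counts plus boundary ties; the divisor is
#' the minimum count in that set. All values are divided by it and the top
#' set is set to exactly 1. Windows with fewer than 10 A/C nucleotides
#' available to define the top 5%, or with a zero divisor, are masked
#' entirely.
#'
#' @param tracks Tibble `gene_id`, `position` (0-based nt within the gene
#'   sequence), `count` of raw DMS counts.
#' @param genes Gene table; the sequence used is `utr5 + cds + utr3` where
#'   UTRs are present, else the CDS.
#' @param window Window size in nt (default 150).
#' @return An object of class `dms_reactivity`: tibble `reactivity`
#'   (gene_id, position, base, reactivity, masked) and a `window_log` tibble
#'   recording every window and masking reason.
#' @export
normalize_dms <- function(tracks, genes, window = 150L) {
  seqs <- gene_sequence(genes)
  out <- vector("list", nrow(seqs))
  logs <- vector("list", nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    id <- seqs$gene_id[i]
    sq <- seqs$seq[i]
    n <- nchar(sq)
    tr <- tracks[tracks$gene_id == id, ]
    if (nrow(tr) == 0) next
    counts <- rep(NA_real_, n)
    pos_ok <- tr$position >= 0 & tr$position < n
    counts[tr$position[pos_ok] + 1L] <- tr$count[pos_ok]
    bases <- strsplit(sq, "")[[1]]
    starts <- seq(1L, n, by = window)
    reactivity <- rep(NA_real_, n)
    masked <- rep(TRUE, n)
    wlog <- vector("list", length(starts))
    for (wi in seq_along(starts)) {
      lo <- starts[wi]; hi <- min(lo + window - 1L, n)
      idx <- lo:hi
      ac <- idx[bases[idx] %in% c("A", "C") & !is.na(counts[idx])]
      reason <- NA_character_
      if (length(ac) < 10) {
        # too few A/C nucleotides to define the top 5%
        reason <- "too_few_ac"
      } else {
        k <- ceiling(0.05 * length(ac))
        cts <- counts[ac]
        thr <- sort(cts, decreasing = TRUE)[k]
        top <- ac[cts >= thr]
        if (thr <= 0) {
          reason <- "zero_divisor"
        } else {
          vals <- counts[idx] / thr
          vals[idx %in% top] <- 1
          vals <- pmin(vals, 1)
          reactivity[idx] <- vals
          masked[idx] <- is.na(vals)
        }
      }
      wlog[[wi]] <- tibble::tibble(gene_id = id, window_start = lo - 1L,
                                   window_end = hi - 1L,
                                   masked = !is.na(reason), reason = reason)
    }
    out[[i]] <- tibble::tibble(
      gene_id = id, position = seq_len(n) - 1L, base = bases,
      reactivity = reactivity, masked = masked
    )
    logs[[i]] <- dplyr::bind_rows(wlog)
  }
  structure(list(reactivity = dplyr::bind_rows(out),
                 window_log = dplyr::bind_rows(logs)),
            class = "dms_reactivity")
}

#' Sliding-window profile of a per-nucleotide signal
#'
#' Averages a per-nucleotide signal (structural energy, DMS reactivity, ...)
#' in sliding windows of `width` nt with stride 1, aligned to the start
#' codon. Window position p covers nucleotides `[p, p + width)`, with p
#' running from `-upstream` to `downstream - 1`. Windows containing any
#' missing value are NA for that gene. Each gene's windows are normalised by
#' the mean over its non-missing windows, then averaged across genes at each
#' position.
#'
#' @param tracks Tibble `gene_id`, `position` (nt relative to the first
#'   nucleotide of the start codon; negative = 5' UTR), `value`.
#' @param width Window width in nt (default 40).
#' @param upstream,downstream Number of window positions upstream (30) and
#'   downstream (250) of the start codon.
#' @return An object of class `dms_windows`: `per_gene` tibble (gene_id,
#'   position, value) of normalised window values and `profile` tibble
#'   (position, mean, n_genes).
#' @export
window_profile <- function(tracks, width = 40L, upstream = 30L,
                           downstream = 250L) {
  positions <- seq(-as.integer(upstream), as.integer(downstream) - 1L)
  per_gene <- tracks %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::group_modify(function(g, key) {
      v <- stats::setNames(g$value, g$position)
      win <- purrr::map_dbl(positions, function(p) {
        need <- as.character(seq(p, p + width - 1L))
        vals <- v[need]
        if (any(is.na(vals)) || length(vals) < width) NA_real_ else mean(vals)
      })
      tibble::tibble(position = positions, value = win)
    }) %>%
    dplyr::ungroup()
  per_gene <- per_gene %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(value = .data$value / mean(.data$value, na.rm = TRUE)) %>%
    dplyr::ungroup() %>%
    dplyr::filter(!is.nan(.data$value))
  profile <- per_gene %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::group_by(.data$position) %>%
    dplyr::summarise(mean = mean(.data$value), n_genes = dplyr::n(),
                     .groups = "drop")
  structure(list(per_gene = per_gene, profile = profile,
                 width = width, upstream = upstream, downstream = downstream),
            class = "dms_windows")
}

#' Correlate window signal with translation efficiency
#'
#' At each window position, the Spearman correlation across genes between
#' the normalised window value and TE, with a conservative Bonferroni
#' correction multiplying each p-value by the number of windows (default
#' 30 upstream + 250 downstream = 280).
#'
#' @param windows A `dms_windows` object.
#' @param te Tibble `gene_id`, `te`.
#' @param n_windows Bonferroni factor; defaults to the number of window
#'   positions in `windows`.
#' @param min_genes Windows with fewer genes are reported as NA (default
#'   10).
#' @return Tibble `position`, `n_genes`, `rho`, `p_raw`, `p_corrected`.
#' @export
te_window_correlation <- function(windows, te, n_windows = NULL,
                                  min_genes = 10L) {
  stopifnot(inherits(windows, "dms_windows"))
  if (is.null(n_windows)) {
    n_windows <- windows$upstream + windows$downstream
  }
  df <- windows$per_gene %>%
    dplyr::inner_join(te, by = "gene_id") %>%
    dplyr::filter(!is.na(.data$value))
  df %>%
    dplyr::group_by(.data$position) %>%
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < min_genes || stats::sd(g$value) == 0 ||
          stats::sd(g$te) == 0) {
        return(tibble::tibble(n_genes = nrow(g), rho = NA_real_,
                              p_raw = NA_real_, p_corrected = NA_real_))
      }
      ct <- suppressWarnings(stats::cor.test(g$value, g$te,
                                             method = "spearman",
                                             exact = FALSE))
      tibble::tibble(n_genes = nrow(g), rho = unname(ct$estimate),
                     p_raw = ct$p.value,
                     p_corrected = min(1, ct$p.value * n_windows))
    }) %>%
    dplyr::ungroup()
}

#' Locate the first energy dip in a window profile
#'
#' Scans downstream of the start codon for positions whose profile value is
#' the minimum within a centred span of `span` nt (`[p - span/2,
#' p + span/2)`), and returns the first such position. On a flat profile the
#' first scanned position is returned (ties broken by smallest coordinate).
#'
#' @param profile Tibble `position`, `mean` (e.g. `windows$profile`), or a
#'   `dms_windows` object.
#' @param span Span width in nt (default 90).
#' @param from First position scanned (default 0, the start codon).
#' @return The nt position of the first dip (NA if no full span exists).
#' @export
find_energy_dip <- function(profile, span = 90L, from = 0L) {
  if (inherits(profile, "dms_windows")) profile <- profile$profile
  pos <- profile$position
  val <- profile$mean
  half <- span %/% 2L
  candidates <- pos[pos >= from]
  for (p in sort(candidates)) {
    in_span <- pos >= max(p - half, from) & pos < p + half
    if (sum(in_span) < 2) next
    if (val[pos == p][1] <= min(val[in_span])) {
      return(p)
    }
  }
  NA_integer_
}

#' Align reactivity tracks to the start codon
#'
#' Shifts per-nucleotide positions from sequence coordinates (0 = first nt
#' of the 5' UTR) to start-codon coordinates (0 = A of the AUG; negative =
#' UTR), dropping masked positions, ready for [window_profile()].
#'
#' @param reactivity A `dms_reactivity` object (or its `reactivity` tibble).
#' @param genes Gene table with `utr5` column.
#' @return Tibble `gene_id`, `position`, `value`.
#' @export
align_to_start <- function(reactivity, genes) {
  if (inherits(reactivity, "dms_reactivity")) {
    reactivity <- reactivity$reactivity
  }
  seqs <- gene_sequence(genes)
  reactivity %>%
    dplyr::filter(!is.na(.data$reactivity)) %>%
    dplyr::left_join(seqs[, c("gene_id", "utr5_len")], by = "gene_id") %>%
    dplyr::transmute(gene_id = .data$gene_id,
                     position = .data$position - .data$utr5_len,
                     value = .data$reactivity)
}
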