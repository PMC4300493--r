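#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Stop codons (DNA alphabet). All internal sequence handling is DNA (T, not U);
# readers normalise U -> T on input.
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons
#'
#' All 64 codons minus the three stop codons, in lexicographic order. This is
#' the parameter index set for global codon dwell times.
#'
#' @return Character vector of length 61.
#' @export
#' @examples
#' length(sense_codons())
sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sort(setdiff(all64, STOP_CODONS))
}

# Normalise a nucleotide string: uppercase, RNA -> DNA.
normalize_nt <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Split a CDS into codons. drop_stop removes a single terminal stop codon
# if present (gene length L_m counts coding codons, not the stop).
cds_codons <- function(cds, drop_stop = TRUE) {
  cds <- normalize_nt(cds)
  n <- nchar(cds)
  if (n < 3L || n %% 3L != 0L) {
    stop("CDS length must be a positive multiple of 3, got ", n, call. = FALSE)
  }
  cod <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  if (drop_stop && cod[length(cod)] %in% STOP_CODONS) {
    cod <- cod[-length(cod)]
  }
  cod
}

# Number of coding codons (excluding a terminal stop, if present).
gene_length_codons <- function(cds) {
  length(cds_codons(cds, drop_stop = TRUE))
}

# Long codon table for a set of genes: one row per (gene, codon position).
# Positions are 0-based.
codon_table <- function(genes) {
  stopifnot(is.data.frame(genes), all(c("gene_id", "cds") %in% names(genes)))
  purrr::map2_dfr(genes$gene_id, genes$cds, function(id, cds) {
    cod <- cds_codons(cds)
    tibble::tibble(
      gene_id = id,
      position = seq_along(cod) - 1L,
      codon = cod
    )
  })
}

# Full mRNA sequence for structure tracks: utr5 + cds + utr3 where present.
gene_sequence <- function(genes) {
  n <- nrow(genes)
  u5 <- if ("utr5" %in% names(genes)) dplyr::coalesce(genes$utr5, "") else rep("", n)
  u3 <- if ("utr3" %in% names(genes)) dplyr::coalesce(genes$utr3, "") else rep("", n)
  tibble::tibble(
    gene_id = genes$gene_id,
    seq = normalize_nt(paste0(u5, genes$cds, u3)),
    utr5_len = nchar(u5)
  )
}

# Deterministic child seed derived from a user seed and a stream label,
# kept below 2^31.
derive_seed <- function(seed, stream) {
  offset <- sum(utf8ToInt(stream)) %% 1000L
  (as.integer(seed) * 1009L + offset * 7L) %% 2147483629L
}
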