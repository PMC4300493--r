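#' Read coding sequences from a FASTA file
#'
#' Reads a FASTA file of coding sequences into a gene table. Sequences are
#' normalised to uppercase DNA (U becomes T). The FASTA identifier (first
#' whitespace-delimited token of the header) becomes `gene_id`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `gene_id` and `cds`.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("Duplicate gene ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(gene_id = ids,
                 cds = unname(normalize_nt(as.character(seqs))))
}

#' Write coding sequences to a FASTA file
#'
#' @param genes Tibble with `gene_id` and `cds`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, path) {
  x <- Biostrings::DNAStringSet(normalize_nt(genes$cds))
  names(x) <- genes$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Format a numeric column so that write -> read round-trips exactly.
fmt_full <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

write_tsv_exact <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double), fmt_full))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# strtod-based parsing: correctly rounded, so "%.17g" output round-trips
# bit for bit (readr's fast float parser can be off by one ulp).
parse_double_exact <- function(x) {
  as.double(x)
}

#' Read a per-codon count table
#'
#' Reads a TSV with columns `gene_id`, `position` (0-based codon index) and
#' `count`. Duplicate (gene, position) pairs and malformed rows are errors.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_id`, `position`, `count`.
#' @export
read_counts_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    position = readr::col_integer(),
    count = readr::col_character()
  ), progress = FALSE)
  df$count <- parse_double_exact(df$count)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    stop("Malformed rows in ", path, " at line(s): ",
         paste(utils::head(prob$row, 5), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[, c("gene_id", "position")])
  if (any(dup)) {
    d <- df[dup, ][1, ]
    stop("Duplicate (gene, position) in ", path, ": ",
         d$gene_id, " position ", d$position, call. = FALSE)
  }
  if (any(df$count < 0)) stop("Negative counts in ", path, call. = FALSE)
  df
}

#' Write a per-codon count table
#'
#' @param counts Tibble with `gene_id`, `position`, `count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  write_tsv_exact(counts[, c("gene_id", "position", "count")], path)
}

#' Read a per-gene abundance table
#'
#' TSV with columns `gene_id` and `abundance` (mRNA transcript level M_m).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_id`, `abundance`.
#' @export
read_abundance_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    abundance = readr::col_character()
  ), progress = FALSE)
  df$abundance <- parse_double_exact(df$abundance)
  if (anyDuplicated(df$gene_id)) stop("Duplicate gene ids in ", path, call. = FALSE)
  df
}

#' Assign the ribosome A-site codon for a footprint read
#'
#' Maps a ribosome-protected fragment to the codon being decoded (the active
#' codon). Reads of length 28–31 nt are used; the offset from the read 5' end
#' to the first nucleotide of the active codon depends on the reading-frame
#' phase of the read start: phase 0 (read begins on the first nucleotide of a
#' codon) gives offset 15, phase 2 (last nucleotide) 16, and phase 1 (middle
#' nucleotide) 17, so the active codon start is always a multiple of 3 within
#' the CDS frame.
#'
#' @param read_start Integer vector: 0-based nucleotide offset of the read 5'
#'   end relative to the first nucleotide of the start codon (may be negative
#'   for reads beginning in the 5' UTR).
#' @param read_length Integer vector of read lengths.
#' @param cds_length_codons Optional integer vector (or scalar) of gene
#'   lengths in codons; when supplied, A-sites falling at or beyond the gene
#'   end are rejected.
#' @return A tibble with columns `read_start`, `read_length`, `codon_index`
#'   (0-based, NA when rejected), `accepted`, `reason`.
#' @export
#' @examples
#' assign_asite(0L, 28L)$codon_index  # 5
#' assign_asite(2L, 30L)$codon_index  # 6
assign_asite <- function(read_start, read_length, cds_length_codons = NULL) {
  n <- max(length(read_start), length(read_length))
  read_start <- as.integer(rep_len(read_start, n))
  read_length <- as.integer(rep_len(read_length, n))
  phase <- ((read_start %% 3L) + 3L) %% 3L
  offset <- dplyr::case_when(
    phase == 0L ~ 15L,
    phase == 2L ~ 16L,
    TRUE ~ 17L
  )
  active_nt <- read_start + offset
  codon_index <- active_nt %/% 3L
  bad_len <- read_length < 28L | read_length > 31L
  reason <- ifelse(bad_len, "read_length_out_of_range", NA_character_)
  if (!is.null(cds_length_codons)) {
    L <- as.integer(rep_len(cds_length_codons, n))
    beyond <- !bad_len & (codon_index >= L | codon_index < 0L)
    reason[beyond] <- "asite_outside_cds"
  }
  accepted <- is.na(reason)
  tibble::tibble(
    read_start = read_start,
    read_length = read_length,
    codon_index = ifelse(accepted, codon_index, NA_integer_),
    accepted = accepted,
    reason = reason
  )
}

#' Read-level filter for mRNA fragments
#'
#' Optional filter for users supplying raw mRNA fragment positions: a
#' fragment is attributed to a gene only if it begins fewer than 16 nt
#' upstream of the start codon and more than 16 nt upstream of the stop
#' codon. Users supplying per-position mRNA counts bypass this.
#'
#' @param read_start 0-based nt offset of fragment start relative to the
#'   first nucleotide of the start codon (negative = upstream).
#' @param cds_length_nt Length of the CDS in nucleotides (including stop).
#' @return Logical vector: keep the fragment?
#' @export
filter_mrna_fragment <- function(read_start, cds_length_nt) {
  read_start > -16 & read_start < cds_length_nt - 3 - 16
}

#' Build footprint profiles from A-site calls
#'
#' Tallies accepted A-site calls into per-codon counts, with an explicit zero
#' for every codon position of every gene.
#'
#' @param asite_calls Tibble with `gene_id` and `codon_index` (0-based).
#' @param genes Gene table with `gene_id`, `cds`.
#' @return A tibble with `gene_id`, `position`, `count` covering every codon
#'   position of every gene in `genes`.
#' @export
build_profiles <- function(asite_calls, genes) {
  grid <- codon_table(genes)[, c("gene_id", "position")]
  calls <- dplyr::inner_join(asite_calls, dplyr::distinct(grid, .data$gene_id),
                             by = "gene_id")
  bad <- dplyr::anti_join(
    dplyr::transmute(asite_calls, gene_id = .data$gene_id,
                     position = as.integer(.data$codon_index)),
    grid, by = c("gene_id", "position")
  )
  if (nrow(bad) > 0) {
    stop("A-site call out of range: gene ", bad$gene_id[1],
         " codon index ", bad$position[1], call. = FALSE)
  }
  tallies <- calls %>%
    dplyr::count(.data$gene_id, position = as.integer(.data$codon_index),
                 name = "count")
  grid %>%
    dplyr::left_join(tallies, by = c("gene_id", "position")) %>%
    dplyr::mutate(count = as.integer(dplyr::coalesce(.data$count, 0L))) %>%
    dplyr::arrange(.data$gene_id, .data$position)
}

#' Apply gene-level quality filters
#'
#' Drops genes that (1) lack an ATG start codon, (2) contain an internal stop
#' codon, (3) have mRNA counts at fewer than 50% of CDS codon positions, or
#' (4) have all-zero footprint counts over the restricted region used for
#' model training. A gene present in `genes` but absent from the count tables
#' is reported with reason `missing_profile`.
#'
#' @param genes Gene table (`gene_id`, `cds`).
#' @param footprints Tibble `gene_id`, `position`, `count` of footprint
#'   counts (0-based codon positions).
#' @param mrna Optional tibble of per-codon mRNA counts in the same format;
#'   when `NULL` the coverage filter is skipped.
#' @return A list with `kept` (filtered gene table) and `report` (tibble
#'   `gene_id`, `kept`, `reasons` — comma-separated rule ids, empty when
#'   kept).
#' @export
filter_genes <- function(genes, footprints, mrna = NULL) {
  reasons <- purrr::map(seq_len(nrow(genes)), function(i) {
    id <- genes$gene_id[i]
    cds <- normalize_nt(genes$cds[i])
    r <- character(0)
    ncod <- nchar(cds) %/% 3L
    cods <- substring(cds, seq(1L, by = 3L, length.out = ncod),
                      seq(3L, by = 3L, length.out = ncod))
    if (cods[1] != "ATG") r <- c(r, "no_aug_start")
    internal <- cods[-c(1L, length(cods))]
    if (any(internal %in% STOP_CODONS)) r <- c(r, "internal_stop")
    fp <- footprints[footprints$gene_id == id, ]
    if (nrow(fp) == 0) {
      r <- c(r, "missing_profile")
    } else {
      L <- gene_length_codons(cds)
      if (!is.null(mrna)) {
        mr <- mrna[mrna$gene_id == id, ]
        covered <- sum(mr$count >= 1)
        if (covered < 0.5 * L) r <- c(r, "low_mrna_coverage")
      }
      kprime <- restricted_positions(L)
      if (length(kprime) > 0) {
        fp_r <- fp$count[fp$position %in% kprime]
        if (length(fp_r) == 0 || all(fp_r == 0)) r <- c(r, "zero_footprints")
      }
    }
    r
  })
  report <- tibble::tibble(
    gene_id = genes$gene_id,
    kept = lengths(reasons) == 0L,
    reasons = purrr::map_chr(reasons, paste, collapse = ",")
  )
  list(kept = genes[report$kept, , drop = FALSE], report = report)
}

#' Assemble per-position profiles for model fitting
#'
#' Joins gene codon identities with footprint (and optionally mRNA) counts
#' into the long profile table consumed by [fit_flow_model()]. Positions
#' absent from the count tables become zeros.
#'
#' @param genes Gene table (`gene_id`, `cds`).
#' @param footprints Tibble `gene_id`, `position`, `count`.
#' @param mrna Optional mRNA count tibble in the same format.
#' @return Tibble `gene_id`, `position`, `codon`, `count` (+ `mrna_count`).
#' @export
prepare_profiles <- function(genes, footprints, mrna = NULL) {
  out <- codon_table(genes) %>%
    dplyr::left_join(footprints, by = c("gene_id", "position")) %>%
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0))
  if (!is.null(mrna)) {
    out <- out %>%
      dplyr::left_join(dplyr::rename(mrna, mrna_count = "count"),
                       by = c("gene_id", "position")) %>%
      dplyr::mutate(mrna_count = dplyr::coalesce(.data$mrna_count, 0))
  }
  dplyr::arrange(out, .data$gene_id, .data$position)
}

#' Write a fitted flow model to TSV tables
#'
#' Writes `global_dwells.tsv` (codon, mu), `gene_dwells.tsv` (gene_id, codon,
#' mu, weight) and `flows.tsv` (gene_id, J) under `dir`, at full double
#' precision so that [read_flow_fit()] round-trips exactly.
#'
#' @param fit A `flow_fit` object from [fit_flow_model()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_flow_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "flow_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_exact(fit$dwell_global, file.path(dir, "global_dwells.tsv"))
  write_tsv_exact(fit$dwell_gene, file.path(dir, "gene_dwells.tsv"))
  write_tsv_exact(fit$flows, file.path(dir, "flows.tsv"))
  invisible(dir)
}

#' Read fitted flow-model tables
#'
#' @param dir Directory written by [write_flow_fit()].
#' @return A list with tibbles `dwell_global`, `dwell_gene`, `flows`.
#' @export
read_flow_fit <- function(dir) {
  read_exact <- function(file, num_cols) {
    df <- readr::read_tsv(file.path(dir, file),
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    for (cl in num_cols) df[[cl]] <- parse_double_exact(df[[cl]])
    df
  }
  list(
    dwell_global = read_exact("global_dwells.tsv", "mu"),
    dwell_gene = read_exact("gene_dwells.tsv", c("mu", "weight")),
    flows = read_exact("flows.tsv", "J")
  )
}
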