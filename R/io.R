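#' @section File dialects:
#' All tables are UTF-8, tab-separated with a header row. CpG islands use
#' 3-column BED (0-based, half-open, no header). Gene TSS coordinates are
#' single 0-based positions.
#' @name io-dialects
#' @keywords internal
NULL

expr_units <- c(
  "raw_counts", "normalized", "uq_normalized", "log2p1", "log2p1_uq",
  "beta", "m_value", "quantile_normalized", "log_abundance"
)

nonneg_units <- c("raw_counts", "normalized", "uq_normalized", "beta")

#' Get or set the unit tag of an expression-like matrix
#'
#' @param m A genes-by-samples numeric matrix.
#' @return The unit tag (a string) or, for the setter, the tagged matrix.
#' @export
expr_unit <- function(m) {
  attr(m, "unit") %||% "raw_counts"
}

#' @rdname expr_unit
#' @param value One of the supported unit tags (see [read_matrix()]).
#' @export
`expr_unit<-` <- function(m, value) {
  value <- arg_match0(value, expr_units)
  attr(m, "unit") <- value
  m
}

#' Read a genes-by-samples matrix from TSV
#'
#' The first column holds gene identifiers; the header row holds sample
#' identifiers. Duplicate gene or sample identifiers and non-numeric cells
#' are hard errors that name the offender.
#'
#' @param path Path to a TSV file.
#' @param unit_tag Unit of the stored values; one of `"raw_counts"`,
#'   `"normalized"`, `"uq_normalized"`, `"log2p1"`, `"log2p1_uq"`, `"beta"`,
#'   `"m_value"`, `"quantile_normalized"`, `"log_abundance"`. Count-like and
#'   beta units must be non-negative and all values finite.
#' @return A numeric matrix with gene rownames, sample colnames and a
#'   `unit` attribute.
#' @export
read_matrix <- function(path, unit_tag = "raw_counts") {
  unit_tag <- arg_match0(unit_tag, expr_units)
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(df) < 2) abort("Matrix file needs a gene-id column plus >=1 sample column.")
  genes <- df[[1]]
  samples <- names(df)[-1]
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g) > 0) {
    abort(sprintf("Duplicate gene id(s): %s", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0) {
    abort(sprintf("Duplicate sample id(s): %s", paste(dup_s, collapse = ", ")))
  }
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & toupper(raw) != "NA")
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-numeric value '%s' at gene '%s', sample '%s'.",
        raw[bad[1]], genes[bad[1]], samples[j]
      ))
    }
    vals[, j] <- num
  }
  if (any(!is.finite(vals))) {
    abort("Matrix contains missing or non-finite values.")
  }
  if (unit_tag %in% nonneg_units && any(vals < 0)) {
    abort(sprintf("Values must be >= 0 for unit '%s'.", unit_tag))
  }
  expr_unit(vals) <- unit_tag
  vals
}

#' Write a genes-by-samples matrix to TSV
#'
#' @param m A numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- tibble::as_tibble(m, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

fold_enum <- function(x, allowed, column, na_value = NULL) {
  x <- tolower(trimws(as.character(x)))
  if (!is.null(na_value)) x[is.na(x) | x == ""] <- na_value
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown token(s) in column '%s': %s (allowed: %s).",
      column, paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
    ))
  }
  x
}

#' Read a sample sheet
#'
#' Expects columns `sample_id` and `tissue_class` (`tumor`/`normal`,
#' case-insensitive) and optional IHC columns `ihc_er`, `ihc_pr`, `ihc_her2`
#' with tokens `pos`/`neg`/`missing`. Absent IHC columns and empty cells are
#' treated as `missing`; unknown tokens are errors.
#'
#' @param path Path to a TSV sample sheet.
#' @return A tibble with columns `sample_id`, `tissue_class`, `ihc_er`,
#'   `ihc_pr`, `ihc_her2`.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  need <- c("sample_id", "tissue_class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("Sample sheet lacks column(s): %s.", paste(miss, collapse = ", ")))
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate sample id(s): %s", paste(dup, collapse = ", ")))
  }
  out <- tibble(
    sample_id = df$sample_id,
    tissue_class = fold_enum(df$tissue_class, c("tumor", "normal"), "tissue_class")
  )
  for (col in c("ihc_er", "ihc_pr", "ihc_her2")) {
    if (col %in% names(df)) {
      out[[col]] <- fold_enum(df[[col]], c("pos", "neg", "missing"), col,
                              na_value = "missing")
    } else {
      out[[col]] <- "missing"
    }
  }
  out
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(sheet, path, progress = FALSE)
  invisible(path)
}

#' Read CpG islands from BED3
#'
#' Intervals are 0-based, half-open `[start, end)`. Negative coordinates and
#' `end <= start` are errors.
#'
#' @param path Path to a headerless 3-column BED file.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_islands <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end"),
    col_types = "cdd",
    progress = FALSE
  )
  validate_islands(df)
  tibble::as_tibble(df)
}

validate_islands <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(!is.finite(df$start)) || any(!is.finite(df$end))) {
    abort("Island coordinates must be finite numbers.")
  }
  if (any(df$start < 0)) abort("Negative island coordinate.")
  bad <- which(df$end <= df$start)
  if (length(bad) > 0) {
    abort(sprintf("Island with end <= start at line %d.", bad[1]))
  }
  invisible(df)
}

#' @rdname read_islands
#' @param islands A tibble with columns `chrom`, `start`, `end`.
#' @export
write_islands <- function(islands, path) {
  validate_islands(islands)
  readr::write_tsv(islands[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene TSS annotation table
#'
#' Columns: `gene_id`, `chrom`, `tss` (0-based single-base transcription
#' start coordinate) and `strand` (`+`/`-`). Strand is carried through but
#' only the TSS coordinate is used for probe-to-gene mapping.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccdc", progress = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("Gene annotation lacks column(s): %s.", paste(miss, collapse = ", ")))
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene id(s): %s", paste(dup, collapse = ", ")))
  }
  if (any(!is.finite(df$tss)) || any(df$tss < 0)) {
    abort("TSS coordinates must be finite and >= 0.")
  }
  bad <- setdiff(unique(df$strand), c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown strand token(s): %s.", paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(df[, need])
}

#' @rdname read_gene_annotation
#' @param annotation A gene-annotation tibble.
#' @export
write_gene_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path, progress = FALSE)
  invisible(path)
}

#' Read per-gene target annotations for the triage cascade
#'
#' Columns: `gene_id`, `pub_count` (non-negative integer), `has_structure`
#' and `structure_druggable` (logical or 0/1), `ligand_percentile` (0-100 or
#' missing). Missing percentiles are allowed and fail the percentile gate.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per annotated gene.
#' @export
read_target_annotations <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      pub_count = readr::col_double(),
      has_structure = readr::col_logical(),
      structure_druggable = readr::col_logical(),
      ligand_percentile = readr::col_double()
    ),
    progress = FALSE
  )
  need <- c("gene_id", "pub_count", "has_structure", "structure_druggable",
            "ligand_percentile")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("Target annotation lacks column(s): %s.", paste(miss, collapse = ", ")))
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene id(s): %s", paste(dup, collapse = ", ")))
  }
  if (any(df$pub_count < 0, na.rm = TRUE)) abort("`pub_count` must be >= 0.")
  pct <- df$ligand_percentile
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    abort("`ligand_percentile` must lie in [0, 100].")
  }
  tibble::as_tibble(df[, need])
}

#' @rdname read_target_annotations
#' @param annotations A target-annotation tibble.
#' @export
write_target_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}
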