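#' Read a gene-by-sample FPKM table with its sample metadata
#'
#' The expression table is TSV with one header row: first column `gene_id`,
#' remaining columns one per sample, entries linear-scale FPKM. Sample
#' metadata is a second TSV keyed by `sample_id` with columns `line_id`,
#' `sex` (`"F"`/`"M"`), `sex_transformed` (logical), `tissue`
#' (`"whole"`/`"head"`), `replicate` (positive integer).
#'
#' Every sample column must be described in the metadata, gene ids must be
#' unique, and all FPKM values must be finite and non-negative.
#'
#' @param path path to the expression TSV.
#' @param metadata_path path to the sample-metadata TSV.
#' @return A long tibble with one row per (gene, sample): columns `gene_id`,
#'   `sample_id`, `line_id`, `sex`, `sex_transformed`, `tissue`, `replicate`,
#'   `fpkm`.
#' @seealso [write_expression()], [read_gene_annotation()], [read_intervals()]
#' @export
read_expression <- function(path, metadata_path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(wide)[1] != "gene_id") {
    abort("expression table must have 'gene_id' as its first column")
  }
  if (anyNA(wide$gene_id) || anyDuplicated(wide$gene_id)) {
    abort("gene_id column contains missing or duplicated ids")
  }
  samples <- read_sample_info(metadata_path)
  expr <- tidyr::pivot_longer(wide, -"gene_id",
                              names_to = "sample_id", values_to = "fpkm")
  validate_fpkm(expr$fpkm)
  unknown <- setdiff(unique(expr$sample_id), samples$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("samples absent from metadata: ",
                 paste(unknown, collapse = ", ")))
  }
  dplyr::inner_join(expr, samples, by = "sample_id") |>
    dplyr::relocate("fpkm", .after = dplyr::last_col())
}

#' Read a sample-metadata table
#'
#' @param path TSV with columns `sample_id`, `line_id`, `sex`,
#'   `sex_transformed`, `tissue`, `replicate`.
#' @return tibble of validated sample records.
#' @export
read_sample_info <- function(path) {
  samples <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                             col_types = readr::cols(
                               sample_id = readr::col_character(),
                               line_id = readr::col_character(),
                               sex = readr::col_character(),
                               sex_transformed = readr::col_logical(),
                               tissue = readr::col_character(),
                               replicate = readr::col_integer()
                             ))
  validate_sample_info(samples)
}

validate_sample_info <- function(samples) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "line_id", "sex", "sex_transformed",
            "tissue", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample metadata lacks columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in metadata")
  if (!all(samples$sex %in% c("F", "M"))) abort("sex must be 'F' or 'M'")
  if (!all(samples$tissue %in% c("whole", "head"))) {
    abort("tissue must be 'whole' or 'head'")
  }
  if (any(samples$replicate < 1)) abort("replicate must be a positive integer")
  key <- samples[c("line_id", "sex", "sex_transformed", "tissue", "replicate")]
  if (anyDuplicated(key)) {
    abort("(line_id, sex, sex_transformed, tissue, replicate) must be unique")
  }
  samples
}

validate_fpkm <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("FPKM values must be numeric and finite")
  }
  if (any(x < 0)) abort("FPKM values must be non-negative")
  invisible(x)
}

#' Write an expression cohort back to TSV
#'
#' Inverse of [read_expression()]: writes the wide gene-by-sample table and,
#' optionally, the sample metadata. Round-tripping preserves values to float
#' precision and metadata exactly.
#'
#' @param expr long expression tibble as returned by [read_expression()].
#' @param path output path for the expression TSV.
#' @param metadata_path optional output path for the sample metadata TSV.
#' @return `expr`, invisibly.
#' @export
write_expression <- function(expr, path, metadata_path = NULL) {
  wide <- expr |>
    dplyr::select("gene_id", "sample_id", "fpkm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "fpkm")
  readr::write_tsv(wide, path, progress = FALSE)
  if (!is.null(metadata_path)) {
    meta <- expr |>
      dplyr::distinct(.data$sample_id, .data$line_id, .data$sex,
                      .data$sex_transformed, .data$tissue, .data$replicate)
    readr::write_tsv(meta, metadata_path, progress = FALSE)
  }
  invisible(expr)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `arm`, `start`, `end` (0-based half-open
#' base-pair coordinates) and optional `tau` (tissue-specificity in
#' \[0, 1\]), `ebox`, `nsl_activated` (logicals) and `is_spike_in`. Missing
#' tau/ebox/nsl values are allowed and exclude the gene from the
#' corresponding stratified analyses only.
#'
#' @param path TSV path.
#' @return tibble of validated gene records.
#' @export
read_gene_annotation <- function(path) {
  genes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_gene_annotation(genes)
}

valid_arms <- c("2L", "2R", "3L", "3R", "4", "X")

validate_gene_annotation <- function(genes) {
  genes <- tibble::as_tibble(genes)
  need <- c("gene_id", "arm", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    abort(paste0("gene annotation lacks columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene_id in annotation")
  if (!all(genes$arm %in% valid_arms)) {
    abort(paste0("unknown arm; expected one of ", paste(valid_arms, collapse = ", ")))
  }
  if (any(genes$start >= genes$end)) abort("gene intervals require start < end")
  if ("tau" %in% names(genes)) {
    tau <- genes$tau[!is.na(genes$tau)]
    if (any(tau < 0 | tau > 1)) abort("tau must lie in [0, 1]")
  }
  if (!"is_spike_in" %in% names(genes)) genes$is_spike_in <- FALSE
  genes$is_spike_in[is.na(genes$is_spike_in)] <- FALSE
  genes
}

#' Read deletion intervals or occupancy peaks from BED
#'
#' BED3/BED4, tab-separated, no header; coordinates are 0-based half-open and
#' are kept in that convention throughout the package. Deficiency (`kind =
#' "df"`) records require the 4th (name) column, taken as the line id, and at
#' most one interval per line.
#'
#' @param path BED path.
#' @param kind `"df"` for deficiency deletion intervals, `"peak"` for
#'   occupancy peak intervals.
#' @param name for peaks, the peak-set label stored in the `name` attribute
#'   (e.g. `"MOF"`).
#' @return For `"df"`: tibble `line_id`, `arm`, `start`, `end`. For
#'   `"peak"`: tibble `arm`, `start`, `end` with a `name` attribute.
#' @export
read_intervals <- function(path, kind = c("df", "peak"), name = "peaks") {
  kind <- match.arg(kind)
  # read everything as character: arm names like "2L" must not be taken
  # as integer literals
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#",
                         col_types = readr::cols(
                           .default = readr::col_character()))
  if (ncol(bed) < 3) abort("BED input needs at least 3 columns")
  out <- tibble::tibble(arm = as.character(bed[[1]]),
                        start = as.numeric(bed[[2]]),
                        end = as.numeric(bed[[3]]))
  if (!all(out$arm %in% valid_arms)) abort("unknown chromosome arm in BED")
  if (any(out$start >= out$end)) abort("BED intervals require start < end")
  if (kind == "df") {
    if (ncol(bed) < 4) abort("Df BED requires a 4th (line_id) column")
    out$line_id <- as.character(bed[[4]])
    if (anyDuplicated(out$line_id)) abort("one deletion interval per line_id")
    out <- dplyr::relocate(out, "line_id")
  } else {
    attr(out, "name") <- name
  }
  out
}

#' Write intervals as BED
#'
#' @param intervals tibble from [read_intervals()] (either kind).
#' @param path output path.
#' @return `intervals`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  cols <- c("arm", "start", "end")
  if ("line_id" %in% names(intervals)) cols <- c(cols, "line_id")
  bed <- intervals[cols]
  bed$start <- format(bed$start, scientific = FALSE, trim = TRUE)
  bed$end <- format(bed$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(intervals)
}
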