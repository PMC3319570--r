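#' Read a log2 expression matrix from TSV
#'
#' Expects tab-delimited text with sample identifiers in the first row and
#' probe/gene identifiers in the first column. Values must be finite
#' numbers on the log2 scale; the reader validates rather than repairs:
#' ragged rows, duplicated sample or row identifiers, and non-numeric or
#' missing cells are errors that name the offending location. Values
#' outside the plausible RMA log2 range [0, 20] trigger a warning only.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, rows = probes or genes, columns = samples.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged TSV: line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    stop("duplicated sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "")
  row_ids <- raw[[1]]
  if (anyDuplicated(row_ids)) {
    stop("duplicated row id: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(row_ids, samples))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    loc <- paste0("row '", row_ids[bad[, 1]], "' sample '",
                  samples[bad[, 2]], "'")
    stop("non-numeric or missing value at: ",
         paste(utils::head(loc, 5L), collapse = "; "),
         if (nrow(bad) > 5L) sprintf(" (and %d more)", nrow(bad) - 5L) else "")
  }
  if (any(vals < 0 | vals > 20)) {
    warning("values outside the expected log2 intensity range [0, 20]; ",
            "check that the matrix is RMA/log2 normalized")
  }
  vals
}

#' Read per-sample metadata from TSV
#'
#' @param path TSV with header
#'   `sample_id  setting_id  condition  subgroup  species  compound`.
#'   `condition` must be `control` or `exposed`; `subgroup` and `compound`
#'   may be empty.
#' @return Data frame with one row per sample. Settings with fewer than 3
#'   samples (too few for any correlation) are listed in the
#'   `unusable_settings` attribute.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "setting_id", "condition")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols)) {
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("subgroup", "species", "compound")) {
    if (!opt %in% names(md)) md[[opt]] <- ""
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(md$condition), c("control", "exposed"))
  if (length(bad)) {
    stop("condition must be 'control' or 'exposed'; found: ",
         paste(bad, collapse = ", "))
  }
  md$subgroup[!nzchar(md$subgroup)] <- NA_character_
  md$compound[!nzchar(md$compound)] <- NA_character_
  sizes <- table(md$setting_id)
  attr(md, "unusable_settings") <- names(sizes)[sizes < 3L]
  md
}

#' Read a probe-to-gene map
#'
#' @param path Two-column TSV `probe_id  symbol`.
#' @return Named character vector: names are probe ids, values gene symbols.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("probe map file not found: ", path)
  pm <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(pm) < 2L) stop("probe map must have two columns: probe_id, symbol")
  if (anyDuplicated(pm[[1]])) {
    stop("duplicated probe_id in probe map: ",
         paste(unique(pm[[1]][duplicated(pm[[1]])]), collapse = ", "))
  }
  stats::setNames(pm[[2]], pm[[1]])
}

#' Collapse probes to one row per gene
#'
#' For genes measured by several probes, keeps the probe with the highest
#' mean expression over the setting's normal (control) samples; ties are
#' broken by lexicographic probe id so the collapse is deterministic.
#' Probes absent from the map are dropped and reported.
#'
#' @param matrix Numeric matrix, rows = probes, columns = samples.
#' @param probe_map Named character vector probe id -> gene symbol.
#' @param metadata Optional metadata data frame (see [read_metadata()])
#'   identifying control samples among the matrix columns. When `NULL`, or
#'   when the setting has no control samples, means are taken over all
#'   samples (with a warning in the latter case).
#' @return Matrix with one row per gene (rownames = gene symbols).
#'   Attributes: `dropped_probes` (unmapped probes), `probe_used` (named
#'   map gene -> chosen probe).
#' @export
select_probe_per_gene <- function(matrix, probe_map, metadata = NULL) {
  probes <- rownames(matrix)
  if (is.null(probes)) stop("matrix must have probe rownames")
  mapped <- probes[probes %in% names(probe_map)]
  dropped <- setdiff(probes, mapped)
  if (!length(mapped)) stop("no matrix probe present in the probe map")

  ref_cols <- colnames(matrix)
  if (!is.null(metadata)) {
    ctrl <- metadata$sample_id[metadata$condition == "control"]
    ctrl <- intersect(ref_cols, ctrl)
    if (length(ctrl)) {
      ref_cols <- ctrl
    } else {
      warning("no control samples in this setting; ",
              "probe means taken over all samples")
    }
  }
  means <- rowMeans(matrix[mapped, ref_cols, drop = FALSE])
  genes <- unname(probe_map[mapped])
  ord <- order(genes, -means, mapped, method = "radix")
  keep <- ord[!duplicated(genes[ord])]
  chosen <- mapped[keep]
  out <- matrix[chosen, , drop = FALSE]
  rownames(out) <- genes[keep]
  attr(out, "dropped_probes") <- dropped
  attr(out, "probe_used") <- stats::setNames(chosen, genes[keep])
  out
}

#' Restrict a gene-level matrix to the analysis geneset
#'
#' @param matrix Gene-level matrix (rownames = canonical gene symbols).
#' @param geneset A `geneset` data frame or a character vector of symbols.
#' @return Matrix restricted to geneset genes present on the platform;
#'   attribute `absent` lists geneset genes missing from the matrix.
#' @export
subset_to_geneset <- function(matrix, geneset) {
  symbols <- if (inherits(geneset, "geneset")) geneset$symbol else geneset
  present <- intersect(rownames(matrix), symbols)
  if (!length(present)) stop("no geneset gene present in the matrix")
  out <- matrix[present, , drop = FALSE]
  attr(out, "absent") <- setdiff(symbols, present)
  out
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_matrix()]; first column `id` carries rownames.
#'
#' @param matrix Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
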