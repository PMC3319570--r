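#' Load the packaged analysis geneset
#'
#' Reads the curated 137-gene analysis set: 41 nuclear receptors, 18 histone
#' demethylases, 45 methyltransferases, 7 nuclear-receptor coregulators and
#' 28 genes relevant to endocrine-disruption phenotypes. Two genes (Men1,
#' Paxip1) belong to both the methyltransferase and coregulator categories,
#' so category slots total 139 while unique symbols number 137. Each gene is
#' stored once; its `categories` field lists every category it belongs to.
#'
#' @param path Path to a geneset TSV. Defaults to the fixture shipped with
#'   the package. The file must have columns `symbol`, `categories`
#'   (semicolon-separated), `aliases` (semicolon-separated, possibly empty),
#'   `phenotype_class` and `source`.
#' @return A data frame of class `geneset` with one row per unique symbol
#'   and columns `symbol`, `categories` (list of character vectors),
#'   `aliases` (list of character vectors), `phenotype_class`, `source`.
#' @examples
#' gs <- load_geneset()
#' nrow(gs)            # 137
#' geneset_counts(gs)  # per-category tallies
#' @export
load_geneset <- function(path = system.file("extdata", "geneset.tsv",
                                            package = "coexprofiler")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("geneset fixture not found: ", path)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("symbol", "categories", "aliases", "phenotype_class", "source")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("geneset fixture lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  valid_cat <- c("nuclear_receptor", "demethylase", "methyltransferase",
                 "coregulator", "phenotype")
  for (i in seq_len(nrow(raw))) {
    if (!nzchar(raw$symbol[i]) || !nzchar(raw$categories[i])) {
      stop("malformed geneset row at line ", i + 1L,
           ": empty symbol or categories")
    }
    cats <- strsplit(raw$categories[i], ";", fixed = TRUE)[[1]]
    bad <- setdiff(cats, valid_cat)
    if (length(bad)) {
      stop("malformed geneset row at line ", i + 1L,
           ": unknown category '", bad[1], "'")
    }
  }
  dup <- raw$symbol[duplicated(raw$symbol)]
  if (length(dup)) {
    stop("duplicated symbol(s) in geneset: ", paste(unique(dup), collapse = ", "))
  }
  gs <- data.frame(symbol = raw$symbol, stringsAsFactors = FALSE)
  gs$categories <- strsplit(raw$categories, ";", fixed = TRUE)
  gs$aliases <- lapply(strsplit(raw$aliases, ";", fixed = TRUE),
                       function(a) a[nzchar(a)])
  gs$phenotype_class <- ifelse(nzchar(raw$phenotype_class),
                               raw$phenotype_class, NA_character_)
  gs$source <- raw$source
  # every alias must resolve to exactly one canonical symbol
  alias_flat <- tolower(unlist(gs$aliases))
  if (anyDuplicated(alias_flat)) {
    stop("alias mapped to more than one canonical symbol: ",
         paste(unique(alias_flat[duplicated(alias_flat)]), collapse = ", "))
  }
  if (any(alias_flat %in% tolower(gs$symbol))) {
    stop("alias collides with a canonical symbol")
  }
  class(gs) <- c("geneset", "data.frame")
  gs
}

#' Per-category gene counts
#'
#' Dual-category genes are counted once in each category they belong to,
#' so the counts sum to 139 for the packaged 137-gene set.
#'
#' @param geneset A `geneset` data frame from [load_geneset()].
#' @return Named integer vector of counts per category.
#' @export
geneset_counts <- function(geneset) {
  tab <- table(unlist(geneset$categories))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Symbols belonging to a category
#'
#' @param geneset A `geneset` data frame.
#' @param category One of `"nuclear_receptor"`, `"demethylase"`,
#'   `"methyltransferase"`, `"coregulator"`, `"phenotype"`.
#' @return Character vector of canonical symbols.
#' @export
geneset_symbols <- function(geneset, category = NULL) {
  if (is.null(category)) return(geneset$symbol)
  keep <- vapply(geneset$categories, function(cc) category %in% cc, logical(1))
  geneset$symbol[keep]
}

#' Build an alias lookup table
#'
#' Maps lower-cased legacy symbols and canonical symbols to the canonical
#' symbol, supporting case-insensitive resolution of historical gene names
#' (e.g. the demethylase nomenclature switch Utx -> Kdm6a).
#'
#' @param geneset A `geneset` data frame.
#' @return Named character vector: names are lower-cased known symbols,
#'   values are canonical symbols.
#' @export
alias_table <- function(geneset) {
  canon <- stats::setNames(geneset$symbol, tolower(geneset$symbol))
  ali <- unlist(mapply(function(sym, al) {
    if (length(al)) stats::setNames(rep(sym, length(al)), tolower(al))
    else character(0)
  }, geneset$symbol, geneset$aliases, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  c(canon, ali)
}

#' Canonicalize gene symbols
#'
#' Resolves legacy symbols (case-insensitively) to the current nomenclature,
#' e.g. `"Utx"` or `"AOF2"` become `"Kdm6a"` and `"Kdm1"`. Symbols not
#' present in the table are returned unchanged with a warning; the returned
#' vector carries a logical `unknown` attribute marking them.
#'
#' @param raw Character vector of gene symbols.
#' @param table Alias lookup from [alias_table()]. Defaults to the packaged
#'   geneset's table.
#' @return Character vector of canonical symbols, attribute `unknown`.
#' @export
normalize_symbol <- function(raw, table = alias_table(load_geneset())) {
  if (!length(raw)) return(character(0))
  if (!is.character(raw) || any(is.na(raw)) || any(!nzchar(raw))) {
    stop("gene symbols must be non-empty strings")
  }
  hit <- table[tolower(raw)]
  unknown <- is.na(hit)
  out <- ifelse(unknown, raw, hit)
  names(out) <- NULL
  if (any(unknown)) {
    warning("unrecognized symbol(s) left unchanged: ",
            paste(unique(raw[unknown]), collapse = ", "))
  }
  attr(out, "unknown") <- unname(unknown)
  out
}

#' The gatekeeper coregulator set
#'
#' The six genes operationalizing the gatekeeper model of promoter access
#' control, in which removal of repressive H3K9 methylation by the
#' demethylase Kdm1 gates liganded-receptor recruitment against marks
#' written by Ehmt1/Ehmt2, Prdm2 and Setdb1: Esr2, Ehmt2, Ehmt1, Kdm1,
#' Prdm2, Setdb1.
#'
#' @return Character vector of six canonical symbols.
#' @export
gatekeeper_set <- function() {
  c("Esr2", "Ehmt2", "Ehmt1", "Kdm1", "Prdm2", "Setdb1")
}
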