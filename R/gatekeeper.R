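#' Pairwise network of the gatekeeper set
#'
#' All pairwise correlation edges among the gatekeeper genes present in
#' the matrix (absent members are reported, not an error, because platform
#' coverage differs between arrays).
#'
#' @param matrix Gene-level expression matrix for one setting.
#' @param gatekeeper_genes Character vector, default [gatekeeper_set()].
#' @param method,groups,setting_id,... Passed to [build_network()].
#' @return Edge data frame restricted to gatekeeper pairs; attribute
#'   `absent` lists gatekeeper genes missing from the matrix.
#' @export
gatekeeper_network <- function(matrix, gatekeeper_genes = gatekeeper_set(),
                               method = "pearson", groups = NULL,
                               setting_id = "setting", ...) {
  present <- intersect(gatekeeper_genes, rownames(matrix))
  if (length(present) < 2L) {
    stop("fewer than 2 gatekeeper genes present in the matrix")
  }
  edges <- build_network(matrix[present, , drop = FALSE], method = method,
                         groups = groups, setting_id = setting_id, ...)
  attr(edges, "absent") <- setdiff(gatekeeper_genes, present)
  edges
}

#' Concordance of a phenotype gene with the gatekeeper pattern
#'
#' Correlates one phenotype-relevant gene against (i) the receptor subset
#' (default the estrogen and androgen receptors) and (ii) every gatekeeper
#' gene present on the platform, then assigns a concordance class:
#' \describe{
#'   \item{full}{strong link to at least one receptor AND strong links to
#'     every gatekeeper gene.}
#'   \item{approaching}{at least an approaching link to a receptor AND at
#'     least approaching links to every gatekeeper gene.}
#'   \item{none}{otherwise.}
#' }
#' Class membership uses significance classes only, not the correlation
#' sign: the gatekeeper pattern mixes correlation and anti-correlation,
#' and the signed pattern vector is returned so stricter sign criteria can
#' be applied downstream.
#'
#' @param matrix Gene-level expression matrix for one setting.
#' @param phenotype_gene Symbol; must be a matrix row.
#' @param gatekeeper_genes Default [gatekeeper_set()].
#' @param receptor_subset Default `c("Esr1", "Esr2", "Ar")`, restricted to
#'   platform availability.
#' @param method,groups,... Correlation options, see [build_network()].
#' @return List of class `concordance_profile`: `phenotype_gene`,
#'   `receptor_link`, `pattern` (data frame gene/role/r/p/sig_class),
#'   `concordance_class`.
#' @export
classify_phenotype_gene <- function(matrix, phenotype_gene,
                                    gatekeeper_genes = gatekeeper_set(),
                                    receptor_subset = c("Esr1", "Esr2", "Ar"),
                                    method = "pearson", groups = NULL, ...) {
  if (!phenotype_gene %in% rownames(matrix)) {
    stop("phenotype gene '", phenotype_gene, "' absent from the matrix")
  }
  gk <- setdiff(intersect(gatekeeper_genes, rownames(matrix)), phenotype_gene)
  rec <- setdiff(intersect(receptor_subset, rownames(matrix)), phenotype_gene)
  if (!length(gk)) stop("no gatekeeper gene present in the matrix")
  if (!length(rec)) stop("no receptor of the subset present in the matrix")

  targets <- unique(c(rec, gk))
  pairs <- cbind(phenotype_gene, targets)
  sub <- matrix[unique(c(phenotype_gene, targets)), , drop = FALSE]
  edges <- build_network(sub, method = method, groups = groups,
                         gene_pairs = pairs, ...)
  lookup <- function(g) {
    hit <- (edges$gene_a == phenotype_gene & edges$gene_b == g) |
           (edges$gene_b == phenotype_gene & edges$gene_a == g)
    if (!any(hit)) return(data.frame(r = NA_real_, p = NA_real_,
                                     sig_class = "absent",
                                     stringsAsFactors = FALSE))
    edges[hit, c("r", "p", "sig_class")]
  }
  pat <- do.call(rbind, lapply(targets, lookup))
  pat <- data.frame(gene = targets,
                    role = ifelse(targets %in% gk,
                                  ifelse(targets %in% rec,
                                         "receptor+gatekeeper", "gatekeeper"),
                                  "receptor"),
                    pat, stringsAsFactors = FALSE)
  rownames(pat) <- NULL

  rank_of <- c(absent = 0L, approaching = 1L, strong = 2L)
  rec_rank <- max(rank_of[pat$sig_class[pat$gene %in% rec]])
  gk_min <- min(rank_of[pat$sig_class[pat$gene %in% gk]])
  receptor_link <- c("none", "approaching", "strong")[rec_rank + 1L]
  concordance_class <-
    if (rec_rank == 2L && gk_min == 2L) "full"
    else if (rec_rank >= 1L && gk_min >= 1L) "approaching"
    else "none"

  structure(list(phenotype_gene = phenotype_gene,
                 receptor_link = receptor_link,
                 pattern = pat,
                 concordance_class = concordance_class),
            class = "concordance_profile")
}

#' Tally concordance classes over a set of profiles
#'
#' @param profiles List of `concordance_profile` objects.
#' @return Data frame with one row per class (`full`, `approaching`,
#'   `none`): `count` and `fraction`.
#' @export
concordance_summary <- function(profiles) {
  if (!length(profiles)) stop("need at least one profile")
  cls <- vapply(profiles, function(p) p$concordance_class, character(1))
  levs <- c("full", "approaching", "none")
  counts <- vapply(levs, function(l) sum(cls == l), integer(1))
  data.frame(concordance_class = levs, count = counts,
             fraction = counts / length(cls),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.concordance_profile <- function(x, ...) {
  cat("Phenotype gene:", x$phenotype_gene,
      "| receptor link:", x$receptor_link,
      "| concordance:", x$concordance_class, "\n")
  print(x$pattern)
  invisible(x)
}
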