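#' Edges conserved across biological settings
#'
#' A gene pair is conserved when it is classified `strong` with the same
#' correlation sign in at least `min_settings` settings. Pairs that are
#' strong with opposite signs in different settings are excluded from the
#' conserved list and reported separately (silent sign flips would corrupt
#' the conservation tallies).
#'
#' @param networks Named list of edge data frames (one per setting) as
#'   produced by [build_network()].
#' @param min_settings Minimum number of settings (default 3, matching the
#'   three-or-more-occurrences reporting rule).
#' @return Data frame with `gene_a`, `gene_b`, `sign` (`"+"`/`"-"`),
#'   `n_settings`, `settings` (comma-separated ids), `sign_consistent`
#'   (always `TRUE` for returned rows). Attribute `discordant`: the same
#'   columns for sign-discordant pairs.
#' @export
conserved_edges <- function(networks, min_settings = 3L) {
  if (!length(networks)) stop("no networks supplied")
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    stop("networks must be a named list keyed by setting id")
  }
  strong <- do.call(rbind, lapply(names(networks), function(s) {
    e <- networks[[s]]
    e <- e[e$sig_class == "strong", c("gene_a", "gene_b", "r"), drop = FALSE]
    if (!nrow(e)) return(NULL)
    data.frame(e, setting = s, stringsAsFactors = FALSE)
  }))
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      sign = character(0), n_settings = integer(0),
                      settings = character(0), sign_consistent = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(strong) || !nrow(strong)) {
    attr(empty, "discordant") <- empty
    return(empty)
  }
  key <- paste(strong$gene_a, strong$gene_b, sep = "\t")
  recs <- lapply(split(strong, key), function(d) {
    signs <- ifelse(d$r >= 0, "+", "-")
    data.frame(gene_a = d$gene_a[1], gene_b = d$gene_b[1],
               sign = signs[1],
               n_settings = nrow(d),
               settings = paste(sort(d$setting), collapse = ","),
               sign_consistent = length(unique(signs)) == 1L,
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  rownames(recs) <- NULL
  discordant <- recs[!recs$sign_consistent, , drop = FALSE]
  keep <- recs[recs$sign_consistent & recs$n_settings >= min_settings, ,
               drop = FALSE]
  keep <- keep[order(keep$gene_a, keep$gene_b), , drop = FALSE]
  rownames(keep) <- rownames(discordant) <- NULL
  attr(keep, "discordant") <- discordant
  keep
}

#' Count strong-edge occurrences of a gene across settings
#'
#' Total number of strong edges involving `gene`, summed over all
#' settings — the hub-occurrence statistic used to rank the most connected
#' receptors and modifiers across studies.
#'
#' @param networks Named list of edge data frames.
#' @param gene Gene symbol.
#' @return Integer count (0, with a warning, if the gene appears in no
#'   network's gene universe).
#' @export
occurrence_count <- function(networks, gene) {
  seen <- FALSE
  total <- 0L
  for (e in networks) {
    inv <- e$gene_a == gene | e$gene_b == gene
    if (any(inv)) seen <- TRUE
    total <- total + sum(inv & e$sig_class == "strong")
  }
  if (!seen) {
    warning("gene '", gene, "' absent from every supplied network")
  }
  total
}

#' Compare a hub's strong partners between control and exposed networks
#'
#' Used for hub genes such as the ASCOM linker Ncoa6: which partners are
#' strongly coexpressed with the hub in control samples, in exposed
#' samples, and in both.
#'
#' @param network_control,network_exposed Edge data frames.
#' @param hub Gene symbol of the hub.
#' @param restrict_to Optional character vector (e.g. the nuclear-receptor
#'   symbols) to which partners are restricted.
#' @return List with `partners_control`, `partners_exposed`, `common`
#'   (sorted character vectors) and `counts` (named integer vector).
#' @export
hub_partner_comparison <- function(network_control, network_exposed, hub,
                                   restrict_to = NULL) {
  partners <- function(e, label) {
    inv <- (e$gene_a == hub | e$gene_b == hub)
    if (!any(inv)) {
      warning("hub '", hub, "' absent from the ", label, " network")
      return(character(0))
    }
    e <- e[inv & e$sig_class == "strong", , drop = FALSE]
    p <- ifelse(e$gene_a == hub, e$gene_b, e$gene_a)
    if (!is.null(restrict_to)) p <- intersect(p, restrict_to)
    sort(unique(p))
  }
  pc <- partners(network_control, "control")
  pe <- partners(network_exposed, "exposed")
  common <- intersect(pc, pe)
  list(partners_control = pc, partners_exposed = pe, common = common,
       counts = c(control = length(pc), exposed = length(pe),
                  common = length(common)))
}
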