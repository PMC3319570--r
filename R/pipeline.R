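#' Export a coexpression network
#'
#' Writes an edge list as plain TSV, Cytoscape SIF (`gene_a corr gene_b`),
#' or GraphML (via igraph) with the correlation as numeric edge weight and
#' an optional geneset category as node attribute.
#'
#' @param edges Edge data frame from [build_network()] (non-empty).
#' @param path Output file path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @param geneset Optional `geneset` data frame used to attach node
#'   categories in GraphML output.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("tsv", "sif", "graphml"),
                           geneset = NULL) {
  if (!nrow(edges)) stop("edge list is empty")
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    writeLines(paste(edges$gene_a, "corr", edges$gene_b, sep = "\t"), path)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("gene_a", "gene_b")], directed = FALSE)
    igraph::E(g)$r <- edges$r
    igraph::E(g)$sig_class <- edges$sig_class
    if (!is.null(geneset)) {
      cat_of <- vapply(igraph::V(g)$name, function(s) {
        i <- match(s, geneset$symbol)
        if (is.na(i)) "other" else paste(geneset$categories[[i]],
                                         collapse = ";")
      }, character(1))
      igraph::V(g)$category <- unname(cat_of)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an exported TSV edge list
#'
#' Round-trip reader for [export_network()]'s TSV format.
#'
#' @param path Path to the TSV.
#' @return Edge data frame.
#' @export
read_edges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

validate_run_config <- function(config) {
  defaults <- list(r_min = 0.75, alpha = 0.05, approach_max = 0.10,
                   fc_min = 1.5, min_settings = 3L, method = "pearson",
                   probe_map = NULL, geneset = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (!is.numeric(config$r_min) || config$r_min <= 0 || config$r_min > 1) {
    stop("invalid config: r_min must lie in (0, 1]")
  }
  if (config$alpha <= 0 || config$alpha >= 1) {
    stop("invalid config: alpha must lie in (0, 1)")
  }
  if (config$approach_max <= config$alpha || config$approach_max >= 1) {
    stop("invalid config: approach_max must lie in (alpha, 1)")
  }
  if (config$fc_min < 1) stop("invalid config: fc_min must be >= 1")
  for (f in c("matrix", "metadata")) {
    if (is.null(config[[f]])) stop("invalid config: missing '", f, "' path")
    if (!file.exists(config[[f]])) {
      stop("invalid config: file not found: ", config[[f]])
    }
  }
  config
}

#' Run the full coexpression-profiling pipeline
#'
#' Orchestrates the stages end to end from a configuration (a list or a
#' YAML file): read inputs, collapse probes, restrict to the analysis
#' geneset, build one correlation network per biological setting (partial
#' correlation for settings whose samples carry subgroup labels),
#' cross-setting conservation, gatekeeper profiling of phenotype genes,
#' and two-group moderated-t differential expression for settings with
#' both conditions. All outputs are written under `out_dir`; inputs are
#' never mutated; identical inputs and config give byte-identical tables.
#' Any stage failure aborts with the stage name.
#'
#' Config fields: `matrix`, `metadata` (paths, required), `probe_map`,
#' `geneset` (paths, optional), `method` (`pearson`/`partial`/`auto`;
#' `auto` = partial when a setting has >= 2 subgroup levels), thresholds
#' `r_min`, `alpha`, `approach_max`, `fc_min`, and `min_settings`.
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with the per-setting `networks`, `conservation`,
#'   `profiles`, `de` tables and the paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("coexprofiler %s",
                         as.character(utils::packageVersion("coexprofiler"))),
                 sprintf("thresholds: r_min=%g alpha=%g approach_max=%g fc_min=%g min_settings=%d",
                         config$r_min, config$alpha, config$approach_max,
                         config$fc_min, as.integer(config$min_settings)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  mat <- stage("read_matrix", read_matrix(config$matrix))
  meta <- stage("read_metadata", read_metadata(config$metadata))
  missing_meta <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing_meta)) {
    stop("stage 'read_metadata' failed: samples without metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  gs <- stage("load_geneset",
              if (is.null(config$geneset)) load_geneset()
              else load_geneset(config$geneset))

  settings <- unique(meta$setting_id)
  networks <- list()
  paths <- character(0)
  de_tables <- list()
  setting_mats <- list()
  for (sid in settings) {
    sm <- meta[meta$setting_id == sid, , drop = FALSE]
    m <- mat[, intersect(colnames(mat), sm$sample_id), drop = FALSE]
    sm <- sm[match(colnames(m), sm$sample_id), , drop = FALSE]
    if (ncol(m) < 3L) {
      log_lines <- c(log_lines,
                     sprintf("setting %s: skipped (%d samples < 3)",
                             sid, ncol(m)))
      next
    }
    if (!is.null(config$probe_map)) {
      pm <- stage("read_probe_map", read_probe_map(config$probe_map))
      m <- stage("select_probe_per_gene", select_probe_per_gene(m, pm, sm))
      dp <- attr(m, "dropped_probes")
      if (length(dp)) {
        log_lines <- c(log_lines,
                       sprintf("setting %s: dropped unmapped probes: %s",
                               sid, paste(dp, collapse = ",")))
      }
      rn <- normalize_symbol(rownames(m), alias_table(gs))
      rownames(m) <- rn
    }
    m <- stage("subset_to_geneset", subset_to_geneset(m, gs))
    setting_mats[[sid]] <- m
    ab <- attr(m, "absent")
    if (length(ab)) {
      log_lines <- c(log_lines,
                     sprintf("setting %s: geneset genes absent from platform (%d): %s",
                             sid, length(ab), paste(ab, collapse = ",")))
    }
    has_sub <- !all(is.na(sm$subgroup)) &&
               length(unique(stats::na.omit(sm$subgroup))) > 1L
    method <- config$method
    if (method == "auto") method <- if (has_sub) "partial" else "pearson"
    groups <- if (method == "partial") sm$subgroup else NULL
    net <- stage(paste0("build_network[", sid, "]"),
                 build_network(m, method = method, groups = groups,
                               setting_id = sid, r_min = config$r_min,
                               alpha = config$alpha,
                               approach_max = config$approach_max))
    networks[[sid]] <- net
    p <- file.path(out_dir, sprintf("edges_%s.tsv", sid))
    export_network(net, p, "tsv")
    paths <- c(paths, p)
    log_lines <- c(log_lines,
                   sprintf("setting %s: %d samples, %d genes, %d edges (%d strong, %d approaching), method=%s",
                           sid, ncol(m), nrow(m), nrow(net),
                           sum(net$sig_class == "strong"),
                           sum(net$sig_class == "approaching"), method))

    if (all(c("control", "exposed") %in% sm$condition) &&
        min(table(sm$condition)) >= 2L) {
      de <- stage(paste0("diffexpr[", sid, "]"),
                  run_de(m, sm$condition))
      kept <- de_filter(de, fc_min = config$fc_min, alpha = config$alpha)
      de$passes_filter <- de$gene %in% kept$gene
      de_tables[[sid]] <- de
      pd <- file.path(out_dir, sprintf("de_%s.tsv", sid))
      utils::write.table(format(de, digits = 15, scientific = FALSE,
                                trim = TRUE),
                         pd, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, pd)
      log_lines <- c(log_lines,
                     sprintf("setting %s: %d genes pass DE filter (%d near-miss)",
                             sid, nrow(kept), nrow(attr(kept, "near_miss"))))
    }
  }
  if (!length(networks)) stop("stage 'build_network' failed: no usable setting")

  cons <- stage("conserved_edges",
                conserved_edges(networks,
                                min_settings = config$min_settings))
  pc <- file.path(out_dir, "conservation.tsv")
  utils::write.table(cons, pc, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, pc)

  # gatekeeper concordance for phenotype genes, per setting where possible
  prof_rows <- NULL
  profiles <- list()
  pheno <- geneset_symbols(gs, "phenotype")
  for (sid in names(networks)) {
    m2 <- setting_mats[[sid]]
    if (is.null(m2)) next
    gk_ok <- length(intersect(gatekeeper_set(), rownames(m2))) >= 2L &&
             length(intersect(c("Esr1", "Esr2", "Ar"), rownames(m2))) >= 1L
    if (!gk_ok) next
    for (pg in intersect(pheno, rownames(m2))) {
      pr <- tryCatch(
        classify_phenotype_gene(m2, pg, r_min = config$r_min,
                                alpha = config$alpha,
                                approach_max = config$approach_max),
        error = function(e) NULL)
      if (is.null(pr)) next
      profiles[[paste(sid, pg, sep = ":")]] <- pr
      prof_rows <- rbind(prof_rows,
                         data.frame(setting_id = sid,
                                    phenotype_gene = pg,
                                    pr$pattern,
                                    receptor_link = pr$receptor_link,
                                    concordance_class = pr$concordance_class,
                                    stringsAsFactors = FALSE))
    }
  }
  if (!is.null(prof_rows)) {
    pp <- file.path(out_dir, "gatekeeper_profiles.tsv")
    utils::write.table(format(prof_rows, digits = 15, trim = TRUE), pp,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pp)
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  paths <- c(paths, file.path(out_dir, "run_log.txt"))
  invisible(list(networks = networks, conservation = cons,
                 profiles = profiles, de = de_tables, paths = paths))
}

#' Write a simulated scenario to disk in the pipeline's input formats
#'
#' Convenience wrapper around [simulate_scenario()] that writes
#' `matrix.tsv`, `metadata.tsv` and `truth.tsv` under `out_dir`, ready to
#' feed [run_pipeline()].
#'
#' @param name Scenario name, see [simulate_scenario()].
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Invisible list of the written paths.
#' @export
write_scenario <- function(name, seed, out_dir) {
  sim <- simulate_scenario(name, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pm <- file.path(out_dir, "matrix.tsv")
  write_matrix(round(sim$matrix, 6), pm)
  pmd <- file.path(out_dir, "metadata.tsv")
  md <- sim$metadata
  md$subgroup[is.na(md$subgroup)] <- ""
  md$compound[is.na(md$compound)] <- ""
  utils::write.table(md, pmd, sep = "\t", quote = FALSE, row.names = FALSE)
  pt <- file.path(out_dir, "truth.tsv")
  tr <- do.call(rbind, lapply(names(sim$truth), function(s) {
    te <- sim$truth[[s]]$true_edges
    if (!nrow(te)) return(NULL)
    data.frame(setting_id = s, te, stringsAsFactors = FALSE)
  }))
  if (is.null(tr)) {
    tr <- data.frame(setting_id = character(0), gene_a = character(0),
                     gene_b = character(0), sign = character(0),
                     rho = numeric(0), conditions = character(0))
  }
  utils::write.table(tr, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(matrix = pm, metadata = pmd, truth = pt))
}
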