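#' Pearson correlation with a t-based p-value
#'
#' Computes the sample product-moment correlation and its two-sided
#' p-value from t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of
#' freedom. Perfect correlation (|r| = 1) returns p = 0.
#'
#' @param x,y Numeric vectors of equal length n >= 3, finite values.
#' @return List with elements `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples for correlation")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  r <- stats::cor(x, y)
  list(r = r, p = cor_pvalue(r, n - 2L), n = n)
}

# two-sided p for correlation(s) r at the given residual df
cor_pvalue <- function(r, df) {
  p <- numeric(length(r))
  perfect <- abs(r) >= 1 - 1e-15
  p[perfect] <- 0
  rr <- r[!perfect]
  tt <- abs(rr) * sqrt(df / (1 - rr^2))
  p[!perfect] <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  p
}

#' Partial correlation controlling for a categorical grouping
#'
#' Correlation of the residuals of `x` and `y` after removing the group
#' means (equivalently, partialling out k - 1 indicator covariates for k
#' group levels). The t-test degrees of freedom are reduced accordingly:
#' df = n - 2 - (k - 1). With a single group level this reduces exactly to
#' [pearson_with_p()].
#'
#' @param x,y Numeric vectors of equal length.
#' @param groups Factor or vector of group labels, one per sample.
#' @return List with elements `r`, `p`, `n`, `k_groups`.
#' @export
partial_with_p <- function(x, y, groups) {
  n <- length(x)
  if (length(y) != n || length(groups) != n) {
    stop("x, y and groups must have equal length")
  }
  g <- as.factor(groups)
  k <- nlevels(g)
  df <- n - 2L - (k - 1L)
  if (df <= 0L) stop("not enough samples: df = n - 2 - (k - 1) <= 0")
  rx <- x - stats::ave(x, g)
  ry <- y - stats::ave(y, g)
  if (sum(rx^2) == 0 || sum(ry^2) == 0) {
    stop("undefined correlation: no within-group variance")
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  list(r = r, p = cor_pvalue(r, df), n = n, k_groups = k)
}

#' Classify a correlation against the study thresholds
#'
#' An edge is `strong` when |r| >= 0.75 and p < 0.05 (strictly),
#' `approaching` when |r| >= 0.75 and 0.05 <= p < 0.10, and `absent`
#' otherwise. Vectorized over `r` and `p`.
#'
#' @param r Correlation coefficient(s).
#' @param p Two-sided p-value(s).
#' @param r_min Absolute correlation threshold (default 0.75).
#' @param alpha Significance level (default 0.05, strict).
#' @param approach_max Upper bound of the approaching-significance band
#'   (default 0.10).
#' @return Character vector in `{"strong", "approaching", "absent"}`.
#' @export
classify_edge <- function(r, p, r_min = 0.75, alpha = 0.05,
                          approach_max = 0.10) {
  stopifnot(length(r) == length(p))
  out <- rep("absent", length(r))
  big <- abs(r) >= r_min
  out[big & p < alpha] <- "strong"
  out[big & p >= alpha & p < approach_max] <- "approaching"
  out
}

#' Build the pairwise coexpression network of a setting
#'
#' Computes all pairwise correlations among the matrix rows (genes) over
#' the setting's samples, attaches t-based p-values and the significance
#' class. With `method = "partial"` the samples' subgroup labels (e.g.
#' generation or cell pool) are partialled out as a categorical covariate,
#' at the cost of k - 1 degrees of freedom. Gene pairs with undefined
#' correlation (a zero-variance gene) are omitted and reported in the
#' `omitted` attribute.
#'
#' @param matrix Numeric matrix, rows = genes, columns = samples of one
#'   biological setting.
#' @param method `"pearson"` or `"partial"`.
#' @param groups Subgroup labels, one per column; required for
#'   `method = "partial"`.
#' @param setting_id Label stored on each edge.
#' @param gene_pairs Optional two-column matrix/data frame of symbol pairs
#'   restricting which edges are computed.
#' @param r_min,alpha,approach_max Classification thresholds, see
#'   [classify_edge()].
#' @return Data frame of edges: `gene_a`, `gene_b` (lexicographically
#'   ordered pair), `r`, `p`, `n`, `k_groups`, `method`, `setting_id`,
#'   `sig_class`. Attribute `omitted` lists pairs dropped for zero
#'   variance.
#' @export
build_network <- function(matrix, method = c("pearson", "partial"),
                          groups = NULL, setting_id = "setting",
                          gene_pairs = NULL, r_min = 0.75, alpha = 0.05,
                          approach_max = 0.10) {
  method <- match.arg(method)
  n <- ncol(matrix)
  if (n < 3L) stop("setting skipped: fewer than 3 usable samples")
  if (nrow(matrix) < 2L) stop("need at least 2 genes")
  if (is.null(rownames(matrix))) stop("matrix must have gene rownames")

  if (method == "partial") {
    if (is.null(groups)) stop("method = 'partial' requires groups")
    g <- as.factor(groups)
    k <- nlevels(g)
    df <- n - 2L - (k - 1L)
    if (df <= 0L) stop("not enough samples for partial correlation")
    centred <- matrix - t(apply(matrix, 1L, function(v) stats::ave(v, g)))
  } else {
    k <- 0L
    df <- n - 2L
    centred <- matrix - rowMeans(matrix)
  }

  sds <- sqrt(rowSums(centred^2))
  usable <- sds > 0
  genes <- rownames(matrix)

  cmat <- stats::cor(t(centred[usable, , drop = FALSE]))
  ug <- genes[usable]

  if (is.null(gene_pairs)) {
    idx <- which(upper.tri(cmat), arr.ind = TRUE)
    pair_a <- ug[idx[, 1]]
    pair_b <- ug[idx[, 2]]
    rvals <- cmat[idx]
    omitted <- omitted_pairs(genes, usable)
  } else {
    gene_pairs <- as.matrix(gene_pairs)
    a <- as.character(gene_pairs[, 1])
    b <- as.character(gene_pairs[, 2])
    known <- a %in% genes & b %in% genes & a != b
    ok <- known & a %in% ug & b %in% ug
    pair_a <- a[ok]
    pair_b <- b[ok]
    rvals <- cmat[cbind(pair_a, pair_b)]
    omitted <- cbind(a[known & !ok], b[known & !ok])
  }

  # canonical unordered-pair order
  swap <- pair_a > pair_b
  tmp <- pair_a[swap]; pair_a[swap] <- pair_b[swap]; pair_b[swap] <- tmp
  rvals <- pmin(1, pmax(-1, rvals))
  pvals <- cor_pvalue(rvals, df)
  edges <- data.frame(
    gene_a = pair_a, gene_b = pair_b,
    r = rvals, p = pvals, n = n,
    k_groups = if (method == "partial") k else 0L,
    method = method, setting_id = setting_id,
    sig_class = classify_edge(rvals, pvals, r_min, alpha, approach_max),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), ]
  rownames(edges) <- NULL
  attr(edges, "omitted") <- omitted
  edges
}

omitted_pairs <- function(genes, usable) {
  bad <- genes[!usable]
  if (!length(bad)) return(matrix(character(0), ncol = 2))
  do.call(rbind, lapply(bad, function(b) {
    others <- setdiff(genes, b)
    cbind(pmin(b, others), pmax(b, others))
  }))
}
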