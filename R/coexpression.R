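#' Pairwise squared Pearson correlation of expression profiles
#'
#' Computes the gene-by-gene matrix of squared Pearson correlations across
#' samples. Values are log-transformed (`log(1 + x)`) by default, since
#' expression levels are strongly right-skewed; genes with zero variance
#' after transformation are dropped with a note (correlation is undefined
#' for them).
#'
#' @param x numeric gene-by-sample matrix with row and column names
#'   (non-negative expression levels).
#' @param log_transform apply `log1p` before correlating (default `TRUE`).
#' @return A symmetric matrix of squared correlations with unit diagonal,
#'   restricted to genes with nonzero variance.
#' @export
pairwise_r2 <- function(x, log_transform = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("at least 3 samples are required")
  if (log_transform) x <- log1p(x)
  v <- apply(x, 1, stats::var)
  keep <- v > 0
  if (sum(keep) < 2)
    stop("at least 2 genes with nonzero variance are required")
  if (any(!keep))
    message("pairwise_r2: dropping ", sum(!keep),
            " zero-variance gene(s): ",
            paste(rownames(x)[!keep], collapse = ", "))
  r <- stats::cor(t(x[keep, , drop = FALSE]))
  r2 <- r^2
  diag(r2) <- 1
  r2
}

#' Threshold an r-squared matrix into a co-expression network
#'
#' Edges are classed `strong` when `r2 > strong` and `weak` when
#' `weak < r2 <= strong`; lower values draw no edge. No self-edges.
#' The default thresholds (0.4 / 0.1) follow common practice of showing
#' strong co-expression as bold edges and weaker similarity as dotted
#' edges.
#'
#' @param r2 symmetric squared-correlation matrix (from [pairwise_r2()]).
#' @param strong strong-edge threshold.
#' @param weak weak-edge threshold; must be `< strong`.
#' @return A list of class `"coexpression_network"` with elements `r2`
#'   (the input matrix) and `edges` (data.frame `gene_i`, `gene_j`, `r2`,
#'   `class`, one row per unordered pair above the weak threshold).
#' @export
build_network <- function(r2, strong = 0.4, weak = 0.1) {
  if (weak >= strong) stop("weak threshold must be below strong threshold")
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("r2 must be square")
  genes <- rownames(r2)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(r2)))
  idx <- which(upper.tri(r2), arr.ind = TRUE)
  vals <- r2[idx]
  sel <- vals > weak
  edges <- data.frame(
    gene_i = genes[idx[sel, 1]],
    gene_j = genes[idx[sel, 2]],
    r2 = vals[sel],
    class = ifelse(vals[sel] > strong, "strong", "weak"),
    stringsAsFactors = FALSE)
  edges <- edges[order(-edges$r2), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(r2 = r2, edges = edges, strong = strong, weak = weak),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "co-expression network: %d genes, %d strong (r2 > %g) and %d weak (r2 > %g) edges\n",
    nrow(x$r2), sum(x$edges$class == "strong"), x$strong,
    sum(x$edges$class == "weak"), x$weak))
  invisible(x)
}

#' Average-linkage ordering of genes by co-expression dissimilarity
#'
#' Convenience ordering for heatmap display: hierarchical clustering with
#' average linkage on the dissimilarity `1 - r2`.
#'
#' @param r2 squared-correlation matrix.
#' @return Integer permutation of gene indices.
#' @export
coexpression_order <- function(r2) {
  hc <- stats::hclust(stats::as.dist(1 - r2), method = "average")
  hc$order
}
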