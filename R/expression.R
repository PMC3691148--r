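#' Read a gene expression matrix from TSV
#'
#' Plain TSV with a header row of sample identifiers and gene identifiers in
#' the first column. GEO Series Matrix files are accepted too: `!`-prefixed
#' metadata lines and `#` comments are skipped. Values that fail numeric
#' parsing (including empty fields and `"null"`/`"NA"`) become `NA`.
#'
#' @param path file path or connection
#' @return numeric matrix, genes in rows (rownames), samples in columns
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^[!#]", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) < 2L) stop("expression file has no data rows")
  tab <- utils::read.delim(text = lines, header = TRUE, check.names = FALSE,
                           quote = "\"", stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)])[1:3], collapse = ", "))
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  rownames(vals) <- genes
  vals
}

#' All-pairs Pearson correlations between gene expression profiles
#'
#' Correlations use pairwise-complete observations. Pairs with fewer than
#' `min_samples` complete observations, or with zero variance over the
#' complete observations, are undefined and excluded from the output.
#'
#' @param expr numeric matrix, genes in rows; missing values permitted
#' @param min_samples minimum complete observations per pair (default 10)
#' @return data.frame `gene_a`, `gene_b`, `pcc`, `n_obs`, one row per defined
#'   unordered pair (gene_a < gene_b); self-correlations are excluded
#' @export
pairwise_pcc <- function(expr, min_samples = 10L) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  suppressWarnings(cc <- stats::cor(t(expr), use = "pairwise.complete.obs"))
  obs <- !is.na(expr)
  nobs <- tcrossprod(obs * 1)
  iu <- which(upper.tri(cc), arr.ind = TRUE)
  pcc <- cc[iu]
  n <- nobs[iu]
  ok <- !is.na(pcc) & n >= min_samples
  out <- data.frame(gene_a = rownames(expr)[iu[ok, 1L]],
                    gene_b = rownames(expr)[iu[ok, 2L]],
                    pcc = pcc[ok], n_obs = as.integer(n[ok]),
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
}

#' Build a signed coexpression network by correlation thresholding
#'
#' Gene pairs whose Pearson correlation reaches `pos_threshold` become
#' positive (coexpression) links and those at or below `neg_threshold` become
#' negative (anti-coexpression) links; ties at the threshold are included.
#' Genes with no retained link are excluded from the node set, so the network
#' consists of linked genes only.
#'
#' Correlations are computed blockwise over gene chunks so that only pairs
#' passing a threshold are materialised; results are identical to the naive
#' all-pairs computation.
#'
#' @param expr numeric matrix, genes in rows
#' @param pos_threshold correlation at or above which a pair is a positive
#'   link (default 0.9)
#' @param neg_threshold correlation at or below which a pair is a negative
#'   link (default -0.9)
#' @param min_samples minimum pairwise-complete observations (default 10)
#' @param block_size genes per block in the blockwise sweep
#' @return a [signed_network]
#' @export
build_cen <- function(expr, pos_threshold = 0.9, neg_threshold = -0.9,
                      min_samples = 10L, block_size = 500L) {
  expr <- as.matrix(expr)
  if (!(neg_threshold < 0 && 0 < pos_threshold)) {
    stop("need neg_threshold < 0 < pos_threshold")
  }
  if (pos_threshold > 1 || neg_threshold < -1) {
    stop("thresholds must lie in [-1, 1]")
  }
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  genes <- rownames(expr)
  ng <- nrow(expr)
  obs <- !is.na(expr)
  starts <- seq(1L, ng, by = block_size)
  acc <- vector("list", 0L)
  texpr <- t(expr)
  for (bi in starts) {
    ii <- bi:min(bi + block_size - 1L, ng)
    for (bj in starts[starts >= bi]) {
      jj <- bj:min(bj + block_size - 1L, ng)
      suppressWarnings(
        cc <- stats::cor(texpr[, ii, drop = FALSE], texpr[, jj, drop = FALSE],
                         use = "pairwise.complete.obs"))
      nobs <- tcrossprod(obs[ii, , drop = FALSE] * 1, obs[jj, , drop = FALSE] * 1)
      cc[nobs < min_samples] <- NA_real_
      hit <- which(!is.na(cc) & (cc >= pos_threshold | cc <= neg_threshold),
                   arr.ind = TRUE)
      if (nrow(hit)) {
        ia <- ii[hit[, 1L]]
        ib <- jj[hit[, 2L]]
        keep <- ia < ib   # each unordered pair once, no self pairs
        if (any(keep)) {
          acc[[length(acc) + 1L]] <- data.frame(
            from = genes[ia[keep]], to = genes[ib[keep]],
            sign = ifelse(cc[hit][keep] >= pos_threshold, 1L, -1L),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(acc)) do.call(rbind, acc) else NULL
  signed_network(edges)
}
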