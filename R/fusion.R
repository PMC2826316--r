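#' Configuration for metabolite-transcriptome PLS fusion
#'
#' @param n_components PLS components for the fusion model (the first
#'   component carries the reported loadings).
#' @param n_permutations Y-permutations for the acceptance rule.
#' @param q2_threshold minimum cross-validated Q2 for a significant
#'   correlate.
#' @param n_segments cross-validation segments.
#' @param x_scaling [scaling_spec()] for the expression block
#'   (unit variance by default; pareto also accepted).
#' @param top_k transcripts to list among the top-ranked loadings.
#' @param seed integer seed for the permutation draws (recorded in the
#'   result, since pass/fail depends on them).
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(n_components = 1, n_permutations = 30,
                          q2_threshold = 0.40, n_segments = 7,
                          x_scaling = scaling_spec("unit_variance"),
                          top_k = 10, seed = 1L) {
  if (q2_threshold < 0 || q2_threshold > 1)
    stop("q2_threshold must lie in [0, 1]")
  structure(list(n_components = n_components,
                 n_permutations = n_permutations,
                 q2_threshold = q2_threshold, n_segments = n_segments,
                 x_scaling = x_scaling, top_k = top_k,
                 seed = as.integer(seed)),
            class = "fusion_config")
}

#' PLS fusion of one metabolite with the transcriptome
#'
#' Builds a PLS regression with the expression matrix as the X block and
#' the metabolite's per-sample values (normalized integrals) as the single
#' Y variable, evaluates Q2 by 7-segment cross-validation, and permutes Y
#' `n_permutations` times. The metabolite is accepted as a significant
#' correlate only if its real Q2 exceeds `q2_threshold` AND exceeds every
#' permuted Q2. Component-1 X-weights, ranked by magnitude (ties broken by
#' probeset id), identify the transcripts most strongly associated with the
#' metabolite.
#'
#' @param X samples x genes expression matrix; rownames are sample ids.
#' @param y per-sample metabolite values; if named, names must match
#'   `rownames(X)`.
#' @param metabolite_id label carried into the result.
#' @param config a [fusion_config()].
#' @return object of class `fusion_result`: `metabolite`, `n_components`,
#'   `q2`, `permuted_q2`, `pass`, `loadings` (data.frame probeset, weight,
#'   rank), `top` (the top_k probesets), `seed`.
#' @export
fuse_metabolite <- function(X, y, metabolite_id = "metabolite",
                            config = fusion_config()) {
  X <- as.matrix(X)
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    unmatched <- c(setdiff(names(y), rownames(X)),
                   setdiff(rownames(X), names(y)))
    if (length(unmatched))
      stop("sample ids of X and y do not match: ",
           paste(utils::head(unmatched, 5), collapse = ", "))
    y <- y[rownames(X)]
  }
  if (length(y) != nrow(X)) stop("X and y must be row-aligned")
  y <- as.numeric(y)
  if (stats::sd(y) == 0) stop("metabolite has zero variance: ", metabolite_id)
  val <- permutation_validate(X, y, config$n_components,
                              config$n_permutations, config$seed,
                              config$n_segments, config$x_scaling)
  q2 <- val$real_Q2
  pass <- q2 > config$q2_threshold && q2 > max(val$permuted$Q2)
  sc <- scale_matrix(X, config$x_scaling)
  fit <- fit_pls(sc$X, y - mean(y), config$n_components)
  w <- fit$W[, 1]
  ids <- colnames(sc$X)
  if (is.null(ids)) ids <- as.character(seq_along(w))
  ord <- order(-abs(w), ids)
  loadings <- data.frame(probeset = ids[ord], weight = w[ord],
                         rank = seq_along(w), row.names = NULL,
                         stringsAsFactors = FALSE)
  structure(list(metabolite = metabolite_id,
                 n_components = config$n_components,
                 q2 = q2, permuted_q2 = val$permuted$Q2, pass = pass,
                 loadings = loadings,
                 top = utils::head(loadings$probeset, config$top_k),
                 seed = config$seed),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("fusion_result '%s': Q2 = %.3f (threshold-and-permutation %s)\n",
              x$metabolite, x$q2, if (x$pass) "PASS" else "fail"))
  cat(sprintf("  max permuted Q2 (%d perms) = %.3f; top correlates: %s\n",
              length(x$permuted_q2), max(x$permuted_q2),
              paste(utils::head(x$top, 3), collapse = ", ")))
  invisible(x)
}

#' Fuse every metabolite of a table with the transcriptome
#'
#' Runs [fuse_metabolite()] per metabolite column; zero-variance columns
#' are skipped with a message.
#'
#' @param X samples x genes expression matrix.
#' @param metabolite_table samples x metabolites matrix.
#' @param config a [fusion_config()].
#' @return list with `results` (named list of `fusion_result`) and
#'   `summary` (data.frame: metabolite, q2, max_permuted_q2, pass, top 3
#'   correlates).
#' @export
fuse_all <- function(X, metabolite_table, config = fusion_config()) {
  metabolite_table <- as.matrix(metabolite_table)
  if (ncol(metabolite_table) < 1) stop("need at least one metabolite column")
  results <- list()
  for (m in colnames(metabolite_table)) {
    ym <- metabolite_table[, m]
    if (stats::sd(ym) == 0) {
      message("skipping zero-variance metabolite: ", m)
      next
    }
    results[[m]] <- fuse_metabolite(X, ym, m, config)
  }
  summary <- do.call(rbind, lapply(results, function(r)
    data.frame(metabolite = r$metabolite, q2 = r$q2,
               max_permuted_q2 = max(r$permuted_q2), pass = r$pass,
               top1 = r$top[1], top2 = r$top[2], top3 = r$top[3],
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}

#' Pearson correlation between two genes
#'
#' @param X samples x genes matrix (or genes x samples with
#'   `genes_in_rows = TRUE`).
#' @param gene_a,gene_b gene (column) names.
#' @param genes_in_rows set TRUE if genes are rows.
#' @return Pearson correlation over all samples.
#' @export
gene_gene_correlation <- function(X, gene_a, gene_b, genes_in_rows = FALSE) {
  X <- as.matrix(X)
  if (genes_in_rows) X <- t(X)
  miss <- setdiff(c(gene_a, gene_b), colnames(X))
  if (length(miss)) stop("gene(s) not present: ", paste(miss, collapse = ", "))
  a <- X[, gene_a]; b <- X[, gene_b]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance gene among: ", gene_a, ", ", gene_b)
  stats::cor(a, b)
}
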