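#' Expression set container
#'
#' A probeset x sample expression matrix, its congruent P/M/A detection-flag
#' matrix, and the study design describing the sample columns.
#'
#' @param values positive probeset x sample matrix; columns named by
#'   sample_id.
#' @param flags character matrix of the same shape with entries "P", "M"
#'   or "A".
#' @param design study design ([make_design()]).
#' @return object of class `expression_set`.
#' @export
expression_set <- function(values, flags, design) {
  values <- as.matrix(values)
  flags <- as.matrix(flags)
  validate_design(design)
  if (!identical(dim(values), dim(flags)))
    stop("values and flags matrices differ in shape")
  if (!all(flags %in% c("P", "M", "A")))
    stop("flags must be 'P', 'M' or 'A'")
  if (!identical(colnames(values), design$sample_id))
    stop("value columns must match design sample_ids in order")
  structure(list(values = values, flags = flags, design = design),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d probesets x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Globally normalize array columns to a fixed mean
#'
#' Scales every array (column) so its mean intensity equals `target`
#' (500 by the MAS5 convention), removing array-to-array brightness
#' differences.
#'
#' @param values positive probeset x sample matrix.
#' @param target column mean after normalization.
#' @return normalized matrix.
#' @export
global_normalize <- function(values, target = 500) {
  values <- as.matrix(values)
  cm <- colMeans(values)
  bad <- which(cm <= 0)
  if (length(bad))
    stop("column(s) with non-positive mean: ",
         paste(if (!is.null(colnames(values))) colnames(values)[bad] else bad,
               collapse = ", "))
  sweep(values, 2, target / cm, "*")
}

#' Floor low values and normalize each gene to its median
#'
#' Expression values below `floor` are raised to `floor`, then each
#' probeset (row) is divided by its median across all samples, putting
#' every gene on a common relative scale with median 1.
#'
#' @param values probeset x sample matrix.
#' @param floor minimum expression value before division.
#' @return per-gene normalized matrix.
#' @export
floor_and_median_normalize <- function(values, floor = 0.01) {
  values <- pmax(as.matrix(values), floor)
  med <- apply(values, 1, stats::median)
  values / med
}

#' Detection filter
#'
#' Keeps a probeset only if it has at least `min_present` "P" flags and at
#' least `min_samples` samples with (globally normalized, pre-per-gene)
#' expression of at least `min_value`.
#'
#' @param es an [expression_set()] whose values are on the
#'   globally-normalized scale.
#' @param min_present minimum number of "P" flags.
#' @param min_value expression threshold.
#' @param min_samples minimum number of samples at or above `min_value`.
#' @return character vector of surviving probeset ids.
#' @export
filter_detected <- function(es, min_present = 3, min_value = 90,
                            min_samples = 3) {
  stopifnot(inherits(es, "expression_set"))
  n_p <- rowSums(es$flags == "P")
  n_hi <- rowSums(es$values >= min_value)
  rownames(es$values)[n_p >= min_present & n_hi >= min_samples]
}

cell_medians <- function(values, design) {
  # probesets x (dose, day) cell medians
  cell <- interaction(design$dose, design$day, drop = TRUE, sep = "@")
  vapply(levels(cell), function(cl)
    apply(values[, cell == cl, drop = FALSE], 1, stats::median),
    numeric(nrow(values)))
}

#' Fold-change filter against time-matched controls
#'
#' For each treated (dose > 0, day) cell, the ratio `r` of the treated
#' group median to the time-matched control (dose 0, same day) median is
#' computed per probeset; the probeset is kept if `max(r, 1/r) >=
#' threshold` in at least one cell (change in either direction counts).
#'
#' @param values probeset x sample matrix (any per-gene scaling; the ratio
#'   is scale-invariant).
#' @param design study design; must contain a dose-0 group at every day.
#' @param threshold minimum fold change (default 1.5).
#' @return character vector of surviving probeset ids.
#' @export
filter_foldchange <- function(values, design, threshold = 1.5) {
  values <- as.matrix(values)
  validate_design(design)
  days <- unique(design$day)
  missing_ctl <- days[!vapply(days, function(d)
    any(design$dose == 0 & design$day == d), logical(1))]
  if (length(missing_ctl))
    stop("no control (dose 0) samples at day(s): ",
         paste(missing_ctl, collapse = ", "))
  med <- cell_medians(values, design)
  keys <- strsplit(colnames(med), "@", fixed = TRUE)
  dose_of <- as.numeric(vapply(keys, `[`, character(1), 1))
  day_of <- as.numeric(vapply(keys, `[`, character(1), 2))
  keep <- rep(FALSE, nrow(values))
  for (j in which(dose_of > 0)) {
    ctl <- med[, dose_of == 0 & day_of == day_of[j]]
    r <- med[, j] / ctl
    keep <- keep | pmax(r, 1 / r) >= threshold
  }
  rownames(values)[keep]
}

# residual sums of squares of Y (genes x samples) under the OLS projection
# of a model matrix, for every gene at once
rss_under <- function(Ylog, mm) {
  qr_ <- qr(mm)
  Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  fitted <- (Ylog %*% Q) %*% t(Q)
  rowSums((Ylog - fitted)^2)
}

#' Two-way ANOVA per gene with Benjamini-Hochberg FDR
#'
#' Fits, per probeset, a two-way fixed-effects ANOVA on log2-transformed
#' values with day and dose as categorical factors plus their interaction
#' (sequential sums of squares, dose after day, each term tested against
#' the full-model residual). Treatment-effect and interaction p-values are
#' adjusted by the Benjamini-Hochberg step-up rule; a probeset is called
#' significant if its adjusted treatment p-value is below `alpha`.
#'
#' @param values positive probeset x sample matrix (log2 is taken
#'   internally; set `log_transform = FALSE` if already logged).
#' @param design study design.
#' @param alpha BH-adjusted significance level for the treatment effect.
#' @param log_transform take log2 of the values first.
#' @return data.frame with columns `probeset`, `p_day`, `p_dose`,
#'   `p_interaction`, `padj_dose`, `padj_interaction`, `significant`,
#'   `significant_interaction`.
#' @export
anova2_bh <- function(values, design, alpha = 0.05, log_transform = TRUE) {
  values <- as.matrix(values)
  validate_design(design)
  Y <- if (log_transform) log2(values) else values
  day <- factor(design$day)
  dose <- factor(design$dose)
  cells <- table(day, dose)
  with_int <- all(cells >= 2)
  if (!with_int)
    message("a (dose, day) cell has < 2 replicates; interaction term dropped")
  m0 <- stats::model.matrix(~1, data.frame(day))
  m_day <- stats::model.matrix(~day)
  m_add <- stats::model.matrix(~day + dose)
  m_full <- if (with_int) stats::model.matrix(~day * dose) else m_add
  rss_day <- rss_under(Y, m_day)
  rss_add <- rss_under(Y, m_add)
  rss_full <- if (with_int) rss_under(Y, m_full) else rss_add
  rss_0 <- rss_under(Y, m0)
  df_day <- nlevels(day) - 1
  df_dose <- nlevels(dose) - 1
  df_int <- if (with_int) df_day * df_dose else 0
  df_err <- nrow(design) - (1 + df_day + df_dose + df_int)
  mse <- rss_full / df_err
  f_day <- ((rss_0 - rss_day) / df_day) / mse
  f_dose <- ((rss_day - rss_add) / df_dose) / mse
  p_day <- stats::pf(f_day, df_day, df_err, lower.tail = FALSE)
  p_dose <- stats::pf(f_dose, df_dose, df_err, lower.tail = FALSE)
  if (with_int) {
    f_int <- ((rss_add - rss_full) / df_int) / mse
    p_int <- stats::pf(f_int, df_int, df_err, lower.tail = FALSE)
  } else p_int <- rep(NA_real_, nrow(Y))
  padj_dose <- stats::p.adjust(p_dose, method = "BH")
  padj_int <- if (with_int) stats::p.adjust(p_int, method = "BH")
             else p_int
  data.frame(probeset = rownames(values),
             p_day = p_day, p_dose = p_dose, p_interaction = p_int,
             padj_dose = padj_dose, padj_interaction = padj_int,
             significant = padj_dose < alpha,
             significant_interaction = if (with_int) padj_int < alpha
                                       else NA,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression ratios to time-matched control medians
#'
#' Divides each sample's value by the median of the control (dose 0)
#' samples at the same study day; control samples are reported as ratios
#' too. A ratio of 8.71 means the treated sample expresses the gene
#' 8.71-fold above its time-matched control median.
#'
#' @param values positive probeset x sample matrix.
#' @param design study design with dose-0 groups at every day.
#' @return matrix of ratios, same shape as `values`.
#' @export
ratios_to_control <- function(values, design) {
  values <- as.matrix(values)
  validate_design(design)
  out <- values
  for (d in unique(design$day)) {
    ctl <- design$dose == 0 & design$day == d
    if (!any(ctl)) stop("no control samples at day ", d)
    med <- apply(values[, ctl, drop = FALSE], 1, stats::median)
    if (any(med == 0)) stop("zero control median at day ", d, " for gene(s): ",
                            paste(rownames(values)[med == 0], collapse = ", "))
    idx <- design$day == d
    out[, idx] <- values[, idx, drop = FALSE] / med
  }
  out
}

#' Hierarchical clustering of gene ratio profiles by Pearson distance
#'
#' Distance between two genes is 1 minus the Pearson correlation of their
#' ratio profiles across samples; agglomeration uses average linkage by
#' default.
#'
#' @param ratios probeset x sample ratio matrix (>= 2 genes, each with
#'   positive variance).
#' @param k optional number of flat clusters to cut.
#' @param linkage "average" or "complete".
#' @return list with `hclust` (the dendrogram) and `clusters` (named
#'   integer vector, or NULL if `k` not given).
#' @export
hcluster_pearson <- function(ratios, k = NULL,
                             linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  ratios <- as.matrix(ratios)
  if (nrow(ratios) < 2) stop("need at least 2 genes to cluster")
  v <- apply(ratios, 1, stats::sd)
  if (any(v == 0))
    stop("constant ratio profile for gene(s): ",
         paste(rownames(ratios)[v == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(ratios)))
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc,
       clusters = if (is.null(k)) NULL else stats::cutree(hc, k = k))
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, tests whether the gene list contains more of the term's
#' members than expected by drawing `length(list)` genes from the universe:
#' the upper-tail hypergeometric probability of an overlap at least as
#' large as observed. No multiple-testing correction is applied. A term
#' qualifies if its overlap reaches `min_overlap` and its p-value is below
#' `alpha` (use `min_overlap = 1` for GO-style and `min_overlap = 3` for
#' KEGG-style reporting).
#'
#' @param gene_list character vector of significant genes (subset of
#'   `universe`).
#' @param term_map named list: term id -> character vector of member genes.
#' @param universe all assayed genes.
#' @param min_overlap minimum overlap to qualify.
#' @param alpha p-value cutoff to qualify.
#' @return data.frame with `term`, `term_size`, `overlap`, `p`,
#'   `qualifies`, sorted by p.
#' @export
enrich <- function(gene_list, term_map, universe, min_overlap = 1,
                   alpha = 0.05) {
  extra <- setdiff(gene_list, universe)
  if (length(extra))
    stop("gene_list contains genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  rows <- lapply(names(term_map), function(tm) {
    members <- intersect(term_map[[tm]], universe)
    if (length(members) == 0) {
      message("term with no universe members skipped: ", tm)
      return(NULL)
    }
    ov <- length(intersect(gene_list, members))
    p <- stats::phyper(ov - 1, length(members),
                       length(universe) - length(members),
                       length(gene_list), lower.tail = FALSE)
    data.frame(term = tm, term_size = length(members), overlap = ov, p = p,
               qualifies = ov >= min_overlap && p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}

#' Pathways co-perturbed at the transcript and metabolite level
#'
#' Flags a pathway when at least one of its member genes is differentially
#' expressed and at least one of its member metabolites changed, and lists
#' the intersecting members (with direction of change when provided as
#' named vectors, e.g. `c(hexokinase_D = "down")`).
#'
#' @param de_genes character vector of DE genes, or named character vector
#'   of directions keyed by gene.
#' @param changed_metabolites character vector of changed metabolites, or
#'   named character vector of directions keyed by metabolite.
#' @param pathway_defs named list: pathway -> list(genes = ...,
#'   metabolites = ...).
#' @return data.frame with `pathway`, `n_genes`, `n_metabolites`,
#'   `flagged`, `genes`, `metabolites` (semicolon-joined member:direction
#'   strings).
#' @export
pathway_overlay <- function(de_genes, changed_metabolites, pathway_defs) {
  ids <- function(x) if (is.null(names(x))) x else names(x)
  fmt <- function(x, hits) {
    if (length(hits) == 0) return("")
    if (is.null(names(x))) paste(hits, collapse = ";")
    else paste(sprintf("%s:%s", hits, x[hits]), collapse = ";")
  }
  rows <- lapply(names(pathway_defs), function(pw) {
    def <- pathway_defs[[pw]]
    g <- intersect(ids(de_genes), def$genes)
    m <- intersect(ids(changed_metabolites), def$metabolites)
    data.frame(pathway = pw, n_genes = length(g), n_metabolites = length(m),
               flagged = length(g) >= 1 && length(m) >= 1,
               genes = fmt(de_genes, g),
               metabolites = fmt(changed_metabolites, m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full expression filtering cascade
#'
#' Applies, in order, global normalization to mean 500, the detection
#' filter (>= 3 "P" flags and >= 3 samples at >= 90), flooring and
#' per-gene median normalization, the 1.5-fold-change filter against
#' time-matched controls, and the two-way ANOVA with BH FDR. Each stage
#' only removes probesets.
#'
#' @param es an [expression_set()] of raw values.
#' @param fc_threshold fold-change filter threshold.
#' @param alpha BH-adjusted significance level.
#' @return list with `normalized` (per-gene normalized matrix), `detected`,
#'   `fold_changed`, `anova` (the [anova2_bh()] table on the survivors),
#'   `significant` (probeset ids), `ratios` (ratio matrix of significant
#'   genes).
#' @export
de_cascade <- function(es, fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(inherits(es, "expression_set"))
  glob <- global_normalize(es$values)
  es_g <- expression_set(glob, es$flags, es$design)
  detected <- filter_detected(es_g)
  norm <- floor_and_median_normalize(glob[detected, , drop = FALSE])
  fold_changed <- filter_foldchange(norm, es$design, fc_threshold)
  anova <- anova2_bh(norm[fold_changed, , drop = FALSE], es$design, alpha)
  significant <- anova$probeset[anova$significant]
  ratios <- if (length(significant))
    ratios_to_control(norm[significant, , drop = FALSE], es$design)
  else NULL
  list(normalized = norm, detected = detected, fold_changed = fold_changed,
       anova = anova, significant = significant, ratios = ratios)
}
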