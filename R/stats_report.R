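#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Accepts either raw per-group observations or printed summary statistics
#' (group means, SDs and ns) — for a balanced one-way layout the summaries
#' are sufficient. Computes the overall F test against the pooled
#' within-group variance and two-sided Dunnett-adjusted p-values for each
#' treated group against the control, using the equicorrelated multivariate
#' t distribution with the pooled error degrees of freedom. Flags follow the
#' reporting convention "*" for p < 0.05 and "**" for p < 0.01.
#'
#' @param x either a data.frame of summaries with columns `group`, `mean`,
#'   `sd`, `n`, or a data.frame of raw data with columns `group`, `value`.
#' @param control the control group label (default: the first group).
#' @return list of class `dunnett_result`: `anova` (F, df, p),
#'   `comparisons` (data.frame: group, mean, n, diff, t, p_adj, flag).
#' @export
anova_dunnett <- function(x, control = NULL) {
  if (all(c("group", "value") %in% names(x))) {
    grp <- split(x$value, factor(x$group, levels = unique(x$group)))
    sm <- data.frame(group = names(grp),
                     mean = vapply(grp, mean, numeric(1)),
                     sd = vapply(grp, stats::sd, numeric(1)),
                     n = vapply(grp, length, numeric(1)),
                     stringsAsFactors = FALSE)
  } else if (all(c("group", "mean", "sd", "n") %in% names(x))) {
    sm <- x
  } else {
    stop("x must have columns (group, value) or (group, mean, sd, n)")
  }
  if (nrow(sm) < 2) stop("need at least 2 groups")
  if (any(sm$n < 2)) stop("every group needs n >= 2")
  if (any(sm$sd < 0)) stop("SDs must be non-negative")
  if (is.null(control)) control <- sm$group[1]
  if (!control %in% sm$group) stop("control group not found: ", control)
  ci <- which(sm$group == control)
  N <- sum(sm$n)
  k <- nrow(sm)
  df_err <- N - k
  mse <- sum((sm$n - 1) * sm$sd^2) / df_err
  grand <- sum(sm$n * sm$mean) / N
  ss_between <- sum(sm$n * (sm$mean - grand)^2)
  f <- (ss_between / (k - 1)) / mse
  p_f <- stats::pf(f, k - 1, df_err, lower.tail = FALSE)
  trt <- setdiff(seq_len(k), ci)
  n0 <- sm$n[ci]
  tstat <- (sm$mean[trt] - sm$mean[ci]) / sqrt(mse * (1 / sm$n[trt] + 1 / n0))
  # correlation of the comparison statistics (shared control)
  lam <- sqrt(sm$n[trt] / (sm$n[trt] + n0))
  R <- outer(lam, lam)
  diag(R) <- 1
  p_adj <- vapply(tstat, function(tv) {
    pr <- mvtnorm::pmvt(lower = rep(-abs(tv), length(trt)),
                        upper = rep(abs(tv), length(trt)),
                        corr = R, df = df_err,
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-6),
                        seed = 1L)
    max(1 - as.numeric(pr), 0)
  }, numeric(1))
  flag <- ifelse(p_adj < 0.01, "**", ifelse(p_adj < 0.05, "*", ""))
  structure(list(
    anova = data.frame(F = f, df1 = k - 1, df2 = df_err, p = p_f),
    comparisons = data.frame(group = sm$group[trt], mean = sm$mean[trt],
                             n = sm$n[trt], diff = sm$mean[trt] - sm$mean[ci],
                             t = tstat, p_adj = p_adj, flag = flag,
                             row.names = NULL, stringsAsFactors = FALSE),
    control = control),
    class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  cat("Dunnett comparisons vs control '", x$control, "':\n", sep = "")
  print(x$comparisons, digits = 4)
  invisible(x)
}

#' Percent change of a treated mean relative to control
#'
#' `round(100 * (treated - control) / control)` to the nearest integer,
#' halves rounded away from zero.
#'
#' @param control_mean positive control group mean.
#' @param treated_mean treated group mean(s); vectorized.
#' @return integer percent change(s).
#' @export
percent_change <- function(control_mean, treated_mean) {
  if (control_mean <= 0) stop("control_mean must be > 0")
  pc <- 100 * (treated_mean - control_mean) / control_mean
  as.integer(sign(pc) * floor(abs(pc) + 0.5))
}

#' Tally changed lipid species by fatty acid and headgroup class
#'
#' Summarizes an annotated list of significantly changed lipid species (one
#' timepoint) into counts per fatty-acid code and per phospholipid
#' headgroup, split by direction of change, in the format
#' `total (FFA/monoacyl/diacyl)`. A species containing a fatty acid counts
#' once per occurrence — a diacyl species with two identical chains counts
#' twice for that fatty acid (configurable); headgroup rows count each
#' species once.
#'
#' @param species data.frame with columns `class` (`FFA`, `monoacyl`,
#'   `diacyl`), `headgroup` (`GpIns`, `GpEtn`, `GpCho`, `GpGro`, `GpSer`,
#'   `GPA` or `none`), `fa1`, `fa2` ("C:D" codes, `fa2` empty unless
#'   diacyl), `direction` (`up`/`down`).
#' @param double_count_identical count both chains of a diacyl species with
#'   two identical fatty acids.
#' @return data.frame with columns `key`, `kind` (`fatty_acid` or
#'   `headgroup`), `direction`, `total`, `ffa`, `monoacyl`, `diacyl`.
#' @export
tally_lipid_changes <- function(species, double_count_identical = TRUE) {
  cols <- c("class", "headgroup", "fa1", "fa2", "direction")
  miss <- setdiff(cols, names(species))
  if (length(miss)) stop("species is missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(species$class), c("FFA", "monoacyl", "diacyl"))
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  empty_row <- function(key, kind, dir)
    data.frame(key = key, kind = kind, direction = dir, total = 0L,
               ffa = 0L, monoacyl = 0L, diacyl = 0L,
               stringsAsFactors = FALSE)
  rows <- list()
  bump <- function(key, kind, dir, cls, times = 1L) {
    id <- paste(kind, key, dir, sep = "|")
    if (is.null(rows[[id]])) rows[[id]] <<- empty_row(key, kind, dir)
    rows[[id]]$total <<- rows[[id]]$total + times
    col <- c(FFA = "ffa", monoacyl = "monoacyl", diacyl = "diacyl")[cls]
    rows[[id]][[col]] <<- rows[[id]][[col]] + times
  }
  for (i in seq_len(nrow(species))) {
    sp <- species[i, ]
    fas <- c(sp$fa1, sp$fa2)
    fas <- fas[!is.na(fas) & nzchar(fas)]
    if (!double_count_identical) fas <- unique(fas)
    for (fa in fas) bump(fa, "fatty_acid", sp$direction, sp$class)
    if (sp$headgroup != "none")
      bump(sp$headgroup, "headgroup", sp$direction, sp$class)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_row("x", "x", "x")[0, , drop = FALSE])
  rownames(out) <- NULL
  out[order(out$kind, out$key, out$direction), , drop = FALSE]
}
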