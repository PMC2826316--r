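#' Bucket (binning) scheme for 1D NMR spectra
#'
#' A scheme is a chemical-shift range, a fixed bucket width, and a set of
#' exclusion regions (typically residual water). Buckets are left-closed,
#' right-open intervals `[lo, hi)` laid contiguously from `start`; a
#' trailing partial bucket (when the range is not a whole multiple of the
#' width) is dropped, and any bucket overlapping an exclusion region at all
#' is removed entirely.
#'
#' @param start_ppm,end_ppm range of the scheme (start < end).
#' @param width_ppm bucket width (> 0).
#' @param exclusions list of numeric `c(lo, hi)` regions within the range;
#'   must not overlap one another.
#' @return object of class `bucket_scheme`.
#' @seealso [bucket_preset()] for the standard liver-extract, plasma CPMG
#'   and HRMAS schemes.
#' @export
bucket_scheme <- function(start_ppm, end_ppm, width_ppm, exclusions = list()) {
  if (width_ppm <= 0) stop("width_ppm must be > 0")
  if (start_ppm >= end_ppm) stop("start_ppm must be < end_ppm")
  for (ex in exclusions) {
    if (length(ex) != 2 || ex[1] >= ex[2])
      stop("each exclusion must be c(lo, hi) with lo < hi")
    if (ex[1] < start_ppm || ex[2] > end_ppm)
      stop(sprintf("exclusion [%g, %g] outside scheme range", ex[1], ex[2]))
  }
  if (length(exclusions) > 1) {
    ord <- order(vapply(exclusions, `[`, numeric(1), 1))
    exs <- exclusions[ord]
    for (i in seq_len(length(exs) - 1))
      if (exs[[i]][2] > exs[[i + 1]][1])
        stop("exclusion regions overlap")
  }
  structure(list(start_ppm = start_ppm, end_ppm = end_ppm,
                 width_ppm = width_ppm, exclusions = exclusions),
            class = "bucket_scheme")
}

#' Standard bucketing presets
#'
#' * `liver_extract`: 0.01 ppm buckets over 0.20-9.95 ppm, water region
#'   4.72-5.05 ppm excluded (942 buckets).
#' * `plasma_cpmg`: 0.02 ppm buckets over 0.60-8.00 ppm, water region
#'   4.68-5.15 ppm excluded (346 buckets).
#' * `hrmas`: 0.04 ppm buckets over 0.50-5.60 ppm, water region
#'   4.75-5.00 ppm excluded.
#'
#' @param name preset name.
#' @return a [bucket_scheme()].
#' @export
bucket_preset <- function(name = c("liver_extract", "plasma_cpmg", "hrmas")) {
  switch(match.arg(name),
    liver_extract = bucket_scheme(0.20, 9.95, 0.01, list(c(4.72, 5.05))),
    plasma_cpmg   = bucket_scheme(0.60, 8.00, 0.02, list(c(4.68, 5.15))),
    hrmas         = bucket_scheme(0.50, 5.60, 0.04, list(c(4.75, 5.00))))
}

#' Enumerate the bucket intervals of a scheme
#'
#' @param scheme a [bucket_scheme()].
#' @return data.frame with columns `lo`, `hi`, ascending, one row per
#'   retained bucket.
#' @export
build_buckets <- function(scheme) {
  stopifnot(inherits(scheme, "bucket_scheme"))
  w <- scheme$width_ppm
  n_full <- floor((scheme$end_ppm - scheme$start_ppm) / w + 1e-9)
  lo <- scheme$start_ppm + w * (seq_len(n_full) - 1)
  hi <- scheme$start_ppm + w * seq_len(n_full)
  keep <- rep(TRUE, n_full)
  tol <- w * 1e-6
  for (ex in scheme$exclusions)
    keep <- keep & !(lo < ex[2] - tol & hi > ex[1] + tol)
  data.frame(lo = lo[keep], hi = hi[keep])
}

bucket_labels <- function(buckets) sprintf("%.8g-%.8g", buckets$lo, buckets$hi)

# Exact integral of the piecewise-linear interpolant of (x, y) over [a, b],
# evaluated via the exact cumulative trapezoid at interpolated endpoints.
trapz_interval <- function(x, y, a, b) {
  cum <- c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
  Fat <- function(e) {
    i <- findInterval(e, x, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1), length(x) - 1)
    ye <- y[i] + (y[i + 1] - y[i]) * (e - x[i]) / (x[i + 1] - x[i])
    cum[i] + (e - x[i]) * (y[i] + ye) / 2
  }
  Fat(b) - Fat(a)
}

#' Integrate one spectrum into the buckets of a scheme
#'
#' Bucket values are trapezoidal integrals of the intensity trace over each
#' bucket's ppm interval, computed exactly on the piecewise-linear
#' interpolant of the acquired points.
#'
#' @param ppm strictly monotone ppm axis.
#' @param intensity intensity at each ppm point (finite).
#' @param scheme a [bucket_scheme()].
#' @return named numeric vector of bucket integrals (names "lo-hi").
#' @export
bucket_spectrum <- function(ppm, intensity, scheme) {
  if (is.unsorted(ppm, strictly = TRUE)) {
    if (is.unsorted(rev(ppm), strictly = TRUE))
      stop("ppm axis must be strictly monotone")
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  if (min(ppm) > scheme$start_ppm || max(ppm) < scheme$end_ppm)
    stop(sprintf(
      "spectrum (%g-%g ppm) does not span the scheme range; uncovered: [%g, %g]",
      min(ppm), max(ppm),
      if (min(ppm) > scheme$start_ppm) scheme$start_ppm else max(ppm),
      if (min(ppm) > scheme$start_ppm) min(ppm) else scheme$end_ppm))
  b <- build_buckets(scheme)
  vals <- trapz_interval(ppm, intensity, b$lo, b$hi)
  stats::setNames(vals, bucket_labels(b))
}

#' Bucket every spectrum of a spectra_set
#'
#' @param spectra a `spectra_set` from [simulate_spectra()] or
#'   [read_spectra_dir()].
#' @param scheme a [bucket_scheme()].
#' @return a [bucket_table()] in state `"raw"`.
#' @export
bucket_spectra <- function(spectra, scheme) {
  b <- build_buckets(scheme)
  vals <- t(apply(spectra$intensities, 1, function(y)
    trapz_interval(spectra$ppm, y, b$lo, b$hi)))
  colnames(vals) <- bucket_labels(b)
  bucket_table(vals, b, state = "raw", design = spectra$design)
}

#' Sample x bucket integral table
#'
#' @param values samples x buckets matrix of non-negative integrals,
#'   columns labelled "lo-hi".
#' @param buckets data.frame of `lo`, `hi` bucket bounds (pairwise
#'   disjoint, ascending).
#' @param state normalization state: `"raw"`, `"total_10000"` or
#'   `"renormalized"`.
#' @param design optional study design carried along for downstream stages.
#' @return object of class `bucket_table`.
#' @export
bucket_table <- function(values, buckets, state = "raw", design = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(buckets))
    stop("values columns and bucket intervals differ in length")
  if (is.null(colnames(values))) colnames(values) <- bucket_labels(buckets)
  if (nrow(buckets) > 1 && any(buckets$lo[-1] < buckets$hi[-nrow(buckets)] - 1e-12))
    stop("bucket intervals must be pairwise disjoint and ascending")
  structure(list(values = values, buckets = buckets, state = state,
                 design = design),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("bucket_table: %d samples x %d buckets (state: %s)\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' Normalize each row to a constant total integral
#'
#' Every spectrum (row) is scaled so its bucket integrals sum to `target`
#' (10000 by convention), making each bucket a fixed ratio of the total
#' integral and removing overall-concentration differences between samples.
#'
#' @param table a [bucket_table()] or plain samples x features matrix.
#' @param target row total after normalization.
#' @return same type as the input; bucket tables move to state
#'   `"total_10000"`.
#' @export
normalize_total <- function(table, target = 10000) {
  if (inherits(table, "bucket_table")) {
    table$values <- normalize_total(table$values, target)
    table$state <- "total_10000"
    return(table)
  }
  m <- as.matrix(table)
  rs <- rowSums(m)
  bad <- which(rs <= 0)
  if (length(bad))
    stop("row(s) with non-positive total integral: ",
         paste(if (!is.null(rownames(m))) rownames(m)[bad] else bad,
               collapse = ", "))
  m * (target / rs)
}

#' Renormalize after excluding dominant resonance regions
#'
#' Removes every bucket overlapping one of the given ppm regions (e.g. the
#' glucose and glycogen resonances, 3.35-4.05, 4.60-4.72 and 5.20-5.55 ppm
#' for liver extracts, whose large between-animal differences otherwise
#' distort the constant-total normalization) and renormalizes the remaining
#' buckets of each spectrum to the same total.
#'
#' @param table a [bucket_table()] in state `"total_10000"`.
#' @param regions list of numeric `c(lo, hi)` ppm regions.
#' @param target row total after renormalization.
#' @return a [bucket_table()] in state `"renormalized"`.
#' @export
renormalize_excluding <- function(table, regions, target = 10000) {
  stopifnot(inherits(table, "bucket_table"))
  if (table$state != "total_10000")
    stop("renormalize_excluding expects a table in state 'total_10000'")
  if (length(regions) == 0) return(table)
  b <- table$buckets
  keep <- rep(TRUE, nrow(b))
  tol <- min(b$hi - b$lo) * 1e-6
  for (r in regions)
    keep <- keep & !(b$lo < r[2] - tol & b$hi > r[1] + tol)
  if (!any(keep)) stop("exclusion regions would remove every bucket")
  out <- bucket_table(normalize_total(table$values[, keep, drop = FALSE], target),
                      b[keep, , drop = FALSE], state = "renormalized",
                      design = table$design)
  out
}

#' Normalize a GC-MS peak table to a constant total area
#'
#' Identical contract to [normalize_total()] for a samples x peaks matrix of
#' individually integrated peak areas.
#'
#' @param peaks samples x peaks matrix of positive areas.
#' @param target row total after normalization.
#' @return normalized matrix.
#' @export
normalize_peak_table <- function(peaks, target = 10000) {
  normalize_total(as.matrix(peaks), target)
}
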