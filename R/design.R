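#' Build a full-factorial study design
#'
#' Constructs the sample sheet for a dose-response study: every combination
#' of dose and study day receives exactly `n_rep` replicate animals. The
#' default arguments reproduce the canonical 4 doses (0/50/500/1000 ppm
#' phenobarbital in diet) x 4 necropsy days (1/3/7/14) x 5 replicates = 80
#' sample layout.
#'
#' @param n_rep replicates per (dose, day) cell; at least 2 for any
#'   downstream inference (1 is allowed for degenerate layouts).
#' @param doses numeric vector of distinct dietary doses (ppm).
#' @param days numeric vector of distinct necropsy days.
#' @param seed accepted for interface uniformity with the simulators; the
#'   factorial layout is deterministic so the value is ignored.
#' @return a `data.frame` with columns `sample_id`, `dose`, `day`,
#'   `replicate`, one row per sample, ordered by day, then dose, then
#'   replicate.
#' @examples
#' d <- make_design()
#' nrow(d)  # 80
#' @export
make_design <- function(n_rep = 5, doses = c(0, 50, 500, 1000),
                        days = c(1, 3, 7, 14), seed = NULL) {
  if (length(n_rep) != 1 || n_rep < 1) stop("n_rep must be a single integer >= 1")
  if (length(doses) == 0 || length(days) == 0) stop("doses and days must be non-empty")
  dup <- unique(doses[duplicated(doses)])
  if (length(dup)) stop("duplicate dose value(s): ", paste(dup, collapse = ", "))
  dup <- unique(days[duplicated(days)])
  if (length(dup)) stop("duplicate day value(s): ", paste(dup, collapse = ", "))
  grid <- expand.grid(replicate = seq_len(n_rep), dose = doses, day = days,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$day, grid$dose, grid$replicate), , drop = FALSE]
  design <- data.frame(
    sample_id = sprintf("d%g_%gppm_r%d", grid$day, grid$dose, grid$replicate),
    dose = grid$dose,
    day = grid$day,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  rownames(design) <- NULL
  stopifnot(!anyDuplicated(design$sample_id))
  design
}

#' Validate that a data.frame is a usable study design
#' @param design a data.frame with sample_id, dose, day, replicate columns.
#' @return the design, invisibly, after validation.
#' @keywords internal
validate_design <- function(design) {
  need <- c("sample_id", "dose", "day", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("design sample_ids are not unique")
  invisible(design)
}
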