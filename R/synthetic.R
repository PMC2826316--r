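#' Planted effect description
#'
#' A planted effect ties a simulation target (a ppm interval of the spectrum,
#' or a gene name) to a dose-response slope on the log(dose + 1) scale and a
#' per-day multiplier. For a multiplicative effect the expected signal is
#' scaled by `exp(slope * log1p(dose) * day_profile[day])`; for an additive
#' effect the term is added instead. Dose effects are therefore monotone in
#' log(dose + 1) and saturate at high dose, mirroring the near-equal
#' responses observed at 500 and 1000 ppm in this class of study.
#'
#' @param target either a numeric length-2 ppm interval `c(lo, hi)` or a
#'   single gene name.
#' @param slope signed effect per unit log(dose + 1). For a multiplicative
#'   effect, `slope = log(f)/log1p(d)` scales the target by factor `f` at
#'   dose `d` (e.g. `log(0.5)/log1p(1000)` halves it at 1000 ppm).
#' @param day_profile named numeric vector of per-day multipliers of the
#'   effect (names are study days). Days absent from the profile get 0.
#' @param mode `"multiplicative"` or `"additive"`.
#' @return an object of class `planted_effect`.
#' @export
planted_effect <- function(target, slope, day_profile,
                           mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  if (!is.finite(slope)) stop("slope must be finite")
  if (is.null(names(day_profile)))
    stop("day_profile must be named by study day")
  structure(list(target = target, slope = slope,
                 day_profile = day_profile, mode = mode),
            class = "planted_effect")
}

effect_multiplier <- function(effect, dose, day) {
  prof <- effect$day_profile[as.character(day)]
  prof[is.na(prof)] <- 0
  term <- effect$slope * log1p(dose) * unname(prof)
  if (effect$mode == "multiplicative") exp(term) else term
}

#' Simulation ground truth
#'
#' Bundles everything the generators treat as "true": planted dose effects
#' (spectral intervals and genes), gene-metabolite correlation links, and
#' correlated gene pairs, together with the master seed from which every
#' sub-generator deterministically derives its own stream.
#'
#' @param effects list of [planted_effect()] objects.
#' @param gene_metabolite_links data.frame with columns `gene_id`,
#'   `metabolite_id`, `r` (target sample-level Pearson correlation).
#' @param gene_gene_links data.frame with columns `gene_a`, `gene_b`, `r`;
#'   `gene_b` is generated to track the realized values of `gene_a`.
#' @param seed master integer seed.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(effects = list(),
                         gene_metabolite_links = empty_links(),
                         gene_gene_links = empty_pairs(),
                         seed = 1L) {
  if (nrow(gene_metabolite_links) && any(abs(gene_metabolite_links$r) > 1))
    stop("|target r| must be <= 1")
  if (nrow(gene_gene_links) && any(abs(gene_gene_links$r) > 1))
    stop("|target r| must be <= 1")
  structure(list(effects = effects,
                 gene_metabolite_links = gene_metabolite_links,
                 gene_gene_links = gene_gene_links,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

empty_links <- function() {
  data.frame(gene_id = character(), metabolite_id = character(),
             r = numeric(), stringsAsFactors = FALSE)
}
empty_pairs <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             r = numeric(), stringsAsFactors = FALSE)
}

# Synthetic 1H spectral library for an aqueous liver extract: Lorentzian
# lines parametrized by center (ppm), half-width gamma (ppm) and area.
# Chemical shifts are textbook values; areas are arbitrary units chosen so
# sugars dominate the spectrum as they do in liver tissue.
spectral_library <- function() {
  read.table(header = TRUE, text = "
metabolite      center gamma  area
glucose         3.25   0.004  6
glucose         3.41   0.004  8
glucose         3.49   0.004  8
glucose         3.54   0.004  6
glucose         3.73   0.004  10
glucose         3.84   0.004  8
glucose         4.65   0.004  3
glucose         5.23   0.004  3
glycogen        3.62   0.010  12
glycogen        3.82   0.010  12
glycogen        3.98   0.010  10
glycogen        5.41   0.010  8
lactate         1.33   0.003  5
lactate         4.11   0.003  1.6
alanine         1.48   0.003  2
succinate       2.41   0.003  2.5
glutamine       2.14   0.004  1.8
glutamine       2.45   0.004  1.6
glutathione     2.17   0.004  1.2
glutathione     2.55   0.004  1.2
glutathione     2.95   0.004  1.0
creatine        3.03   0.003  2
creatine        3.93   0.003  1.2
taurine         3.27   0.004  2.5
taurine         3.43   0.004  2.5
betaine         3.26   0.003  3
adenosine       6.05   0.004  0.8
adenosine       8.24   0.004  0.6
adenosine       8.35   0.004  0.6
formate         8.46   0.002  0.4
")
}

# Day-wise 1000 ppm fold changes for the default dose-responsive genes,
# magnitudes matching a classical hepatic phenobarbital response (strong
# induction of xenobiotic metabolism, repression of glucokinase and
# glutamine synthetase).
default_gene_fc <- function() {
  read.table(header = TRUE, text = "
gene                              d1    d3    d7    d14
hexokinase_D                      0.23  0.41  0.39  0.40
glutamine_synthetase              0.57  0.39  0.45  0.30
glutamate_cysteine_ligase         1.59  1.80  0.92  1.04
glutathione_reductase             1.57  1.99  1.74  1.61
malic_enzyme                      1.72  1.87  1.71  1.74
aminolevulinate_synthase          3.68  2.29  2.05  1.39
lipoprotein_lipase                1.19  2.32  7.33  5.16
epoxide_hydrolase                 2.57  2.88  2.67  3.33
CYP3A3                            1.74  1.84  1.70  1.81
aldehyde_dehydrogenase_1A1        4.87  9.82 14.11 24.59
UDP_glucuronosyltransferase_PB    4.98  6.71  6.63  5.89
glutathione_S_transferase_Yb4     2.19  9.01  8.44  7.89
CYP2B2                            7.06  9.16  7.01  8.71
")
}

#' Default simulation ground truth
#'
#' The default truth emulates the hallmark hepatic response to dietary
#' phenobarbital: a dose-dependent decrease of glucose and glycogen
#' resonances, an increase of succinate, a decrease of adenosine, transient
#' increases of glutamine and glutathione restricted to days 1-7, thirteen
#' dose-responsive genes with fold-change magnitudes typical of the
#' xenobiotic-metabolism program, one gene tracking succinate at a target
#' Pearson r (the 5-aminolevulinate-synthase-like correlate), and a gene
#' pair correlated at r = 0.7 (the malic enzyme / glutathione reductase
#' motif).
#'
#' @param seed master seed stored in the truth object.
#' @param succinate_r target correlation of the planted succinate-tracking
#'   gene.
#' @param pair_r target correlation of the planted gene pair.
#' @return a [ground_truth()] object.
#' @export
default_truth <- function(seed = 1L, succinate_r = 0.9, pair_r = 0.7) {
  all_days <- c("1" = 1, "3" = 1, "7" = 1, "14" = 1)
  early <- c("1" = 1, "3" = 1, "7" = 1, "14" = 0)
  halve <- log(0.5) / log1p(1000)   # halved at 1000 ppm
  dble <- log(2) / log1p(1000)      # doubled at 1000 ppm
  spectral <- list(
    planted_effect(c(3.35, 4.05), halve, all_days),       # glucose/glycogen CH
    planted_effect(c(4.60, 4.72), halve, all_days),       # glucose anomeric
    planted_effect(c(5.20, 5.55), halve, all_days),       # glucose/glycogen C1H
    planted_effect(c(2.39, 2.43), dble, all_days),        # succinate
    planted_effect(c(6.00, 6.10), log(0.7) / log1p(1000), all_days), # adenosine
    planted_effect(c(2.12, 2.18), log(1.5) / log1p(1000), early),    # glutamine/GSH
    planted_effect(c(2.53, 2.57), log(1.5) / log1p(1000), early)
  )
  fc <- default_gene_fc()
  genes <- lapply(seq_len(nrow(fc)), function(i) {
    lfc <- log(as.numeric(fc[i, c("d1", "d3", "d7", "d14")]))
    ref <- lfc[which.max(abs(lfc))]
    planted_effect(fc$gene[i], ref / log1p(1000),
                   stats::setNames(lfc / ref, c(1, 3, 7, 14)))
  })
  ground_truth(
    effects = c(spectral, genes),
    gene_metabolite_links = data.frame(
      gene_id = "succinate_tracker", metabolite_id = "succinate",
      r = succinate_r, stringsAsFactors = FALSE),
    gene_gene_links = data.frame(
      gene_a = "malic_enzyme", gene_b = "glutathione_reductase_paralog",
      r = pair_r, stringsAsFactors = FALSE),
    seed = seed
  )
}

spectral_effects <- function(truth) {
  Filter(function(e) is.numeric(e$target), truth$effects)
}
gene_effects <- function(truth) {
  Filter(function(e) is.character(e$target), truth$effects)
}

#' Simulate raw 1D NMR spectra for a study design
#'
#' Generates one spectrum per sample on a shared ppm grid. Each synthetic
#' metabolite contributes positive Lorentzian lines on a small positive
#' baseline; planted ppm-interval effects scale every line whose center lies
#' in the interval by `exp(slope * log1p(dose) * day_profile[day])`, so the
#' integrated intensity of the interval is monotone in log(dose + 1) in
#' expectation. Sample-to-sample biological variation is a per-(sample,
#' metabolite) log-normal amplitude factor; instrument noise is additive
#' Gaussian on the intensity trace (floored at a tiny positive value so
#' intensities stay strictly positive).
#'
#' @param design a design from [make_design()].
#' @param truth a [ground_truth()]; its interval effects are applied and its
#'   seed drives the random streams.
#' @param ppm_grid numeric `c(start, end, step)` of the acquisition grid.
#' @param noise_sd standard deviation of the additive intensity noise.
#' @param amp_cv log-normal sd of the per-sample metabolite amplitude
#'   variation (biological variance; the within-group spread it induces is
#'   calibrated so dose models reach the cross-validated Q2 regime typical
#'   of this design, roughly 0.4-0.7).
#' @param baseline constant positive baseline intensity.
#' @return an object of class `spectra_set`: list with `ppm` (grid),
#'   `intensities` (samples x points matrix, rows named by sample_id) and
#'   `design`.
#' @export
simulate_spectra <- function(design, truth = default_truth(),
                             ppm_grid = c(0.2, 10.0, 0.001),
                             noise_sd = 0.02, amp_cv = 0.15,
                             baseline = 0.005) {
  validate_design(design)
  ppm <- seq(ppm_grid[1], ppm_grid[2], by = ppm_grid[3])
  lib <- spectral_library()
  effs <- spectral_effects(truth)
  for (e in effs) {
    if (e$target[1] < ppm_grid[1] || e$target[2] > ppm_grid[2])
      stop(sprintf("effect interval [%g, %g] lies outside the ppm grid [%g, %g]",
                   e$target[1], e$target[2], ppm_grid[1], ppm_grid[2]))
  }
  mets <- unique(lib$metabolite)
  n <- nrow(design)
  intens <- matrix(0, n, length(ppm),
                   dimnames = list(design$sample_id, NULL))
  # precompute unit-area Lorentzian shape per library line
  shapes <- lapply(seq_len(nrow(lib)), function(i) {
    g <- lib$gamma[i]
    (g / pi) / ((ppm - lib$center[i])^2 + g^2)
  })
  withr::with_seed(truth$seed, {
    amps <- matrix(exp(stats::rnorm(n * length(mets), 0, amp_cv)),
                   n, length(mets), dimnames = list(NULL, mets))
    for (s in seq_len(n)) {
      area <- lib$area * amps[s, lib$metabolite]
      for (e in effs) {
        hit <- lib$center >= e$target[1] & lib$center <= e$target[2]
        if (!any(hit)) next
        m <- effect_multiplier(e, design$dose[s], design$day[s])
        if (e$mode == "multiplicative") area[hit] <- area[hit] * m
        else area[hit] <- pmax(area[hit] + m, 0)
      }
      spec <- baseline
      for (i in seq_len(nrow(lib))) spec <- spec + area[i] * shapes[[i]]
      spec <- spec + stats::rnorm(length(ppm), 0, noise_sd)
      intens[s, ] <- pmax(spec, 1e-9)
    }
  })
  structure(list(ppm = ppm, intensities = intens, design = design),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra, %d points, %.2f-%.2f ppm\n",
              nrow(x$intensities), length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Simulate a probeset x sample expression matrix with detection flags
#'
#' Emits, in order: the truth's dose-responsive genes (multiplicative
#' log(dose + 1) fold-change effects with log-normal replicate noise),
#' one gene per gene-metabolite link constructed so its sample-level Pearson
#' correlation with the named metabolite matches the target r (exactly at
#' |r| = 1 with zero residual noise), one partner gene per gene-gene link
#' tracking the realized values of its mate, and `n_null_genes` genes with
#' no dose structure. Detection flags are independent Bernoulli "P" calls
#' (else "A") since only the >= 3-present-flags filter consumes them.
#'
#' @param design study design; rows of `metabolite_table` must align with
#'   it.
#' @param truth a [ground_truth()].
#' @param n_null_genes number of no-effect genes.
#' @param metabolite_table samples x metabolites numeric matrix (or NULL if
#'   the truth has no metabolite links); rownames must match
#'   `design$sample_id` when present.
#' @param base_expr median baseline expression (globally-normalized scale).
#' @param noise_sdlog replicate noise sd on the natural-log scale (~25%
#'   coefficient of variation, typical of 3'-array replicates).
#' @param link_cv relative amplitude of linked-gene variation around its
#'   baseline.
#' @param p_present probability of a "P" detection flag.
#' @return an [expression_set()] with `values`, `flags` and `design`.
#' @export
simulate_expression <- function(design, truth = default_truth(),
                                n_null_genes = 500,
                                metabolite_table = NULL,
                                base_expr = 500, noise_sdlog = 0.25,
                                link_cv = 0.2, p_present = 0.95) {
  validate_design(design)
  n <- nrow(design)
  links <- truth$gene_metabolite_links
  pairs <- truth$gene_gene_links
  if (nrow(links)) {
    if (is.null(metabolite_table))
      stop("truth has gene-metabolite links but no metabolite_table was given")
    metabolite_table <- as.matrix(metabolite_table)
    if (nrow(metabolite_table) != n)
      stop("metabolite_table rows do not align with the design samples")
    unknown <- setdiff(links$metabolite_id, colnames(metabolite_table))
    if (length(unknown))
      stop("link references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  dgenes <- gene_effects(truth)
  withr::with_seed(truth$seed + 1L, {
    rows <- list()
    ldose <- log1p(design$dose)
    for (e in dgenes) {
      mult <- vapply(seq_len(n), function(s)
        effect_multiplier(e, design$dose[s], design$day[s]), numeric(1))
      mu <- base_expr * exp(stats::rnorm(1, 0, 0.3))
      rows[[e$target]] <- mu * mult * exp(stats::rnorm(n, 0, noise_sdlog))
    }
    for (i in seq_len(nrow(links))) {
      m <- metabolite_table[, links$metabolite_id[i]]
      if (stats::sd(m) == 0) stop("linked metabolite has zero variance: ",
                                  links$metabolite_id[i])
      z <- as.numeric(scale(m))
      r <- links$r[i]
      g <- r * z + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
      mu <- base_expr * exp(stats::rnorm(1, 0, 0.3))
      rows[[links$gene_id[i]]] <- pmax(mu * (1 + link_cv * g), 0.01)
    }
    for (i in seq_len(nrow(pairs))) {
      a <- rows[[pairs$gene_a[i]]]
      if (is.null(a))
        stop("gene_gene link references unknown gene: ", pairs$gene_a[i])
      z <- as.numeric(scale(log(a)))
      r <- pairs$r[i]
      g <- r * z + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
      mu <- base_expr * exp(stats::rnorm(1, 0, 0.3))
      rows[[pairs$gene_b[i]]] <- pmax(mu * (1 + link_cv * g), 0.01)
    }
    if (n_null_genes > 0) {
      mu0 <- exp(stats::rnorm(n_null_genes, log(base_expr), 0.6))
      null_mat <- mu0 * matrix(exp(stats::rnorm(n_null_genes * n, 0, noise_sdlog)),
                               n_null_genes, n)
      rownames(null_mat) <- sprintf("null_%04d", seq_len(n_null_genes))
    } else null_mat <- NULL
    values <- rbind(do.call(rbind, rows), null_mat)
    colnames(values) <- design$sample_id
    flags <- matrix(ifelse(stats::runif(length(values)) < p_present, "P", "A"),
                    nrow(values), ncol(values), dimnames = dimnames(values))
  })
  expression_set(values, flags, design)
}

# Fatty-acid codes observed in hepatic glycerophospholipid profiling,
# weighted toward the abundant 16:0/18:0/18:1/18:2/20:4/22:6 species.
lipid_fa_codes <- function() {
  c("14:0", "16:0", "16:1", "17:0", "18:0", "18:1", "18:2", "18:3",
    "20:0", "20:1", "20:2", "20:3", "20:4", "20:5", "22:0", "22:4",
    "22:5", "22:6")
}

#' Simulate an annotated list of significantly changed lipid species
#'
#' Produces the input expected by [tally_lipid_changes()]: one row per
#' changed species and timepoint with its structural class (free fatty
#' acid, monoacyl- or diacyl-glycerophospholipid), headgroup, one or two
#' fatty acids coded "C:D", and the direction of change. Direction
#' probabilities encode the characteristic remodelling pattern (GpIns
#' species mostly up, GpEtn/GpCho mostly down, arachidonate-containing
#' species down).
#'
#' @param seed integer seed; identical seeds give identical tables.
#' @param n_species changed species per timepoint.
#' @param days timepoints to emit.
#' @return data.frame with columns `species_id`, `class`, `headgroup`,
#'   `fa1`, `fa2`, `direction`, `day`.
#' @export
simulate_lipid_changes <- function(seed = 1L, n_species = 60,
                                   days = c(3, 7, 14)) {
  fas <- lipid_fa_codes()
  wts <- c(1, 8, 2, 1, 8, 5, 4, 1, 1, 1, 1, 2, 6, 2, 1, 1, 2, 4)
  hgs <- c("GpIns", "GpEtn", "GpCho", "GpGro", "GpSer", "GPA")
  up_prob <- c(GpIns = 0.85, GpEtn = 0.1, GpCho = 0.25, GpGro = 0.6,
               GpSer = 0.2, GPA = 0.5, none = 0.55)
  withr::with_seed(as.integer(seed), {
    out <- lapply(days, function(day) {
      cls <- sample(c("FFA", "monoacyl", "diacyl"), n_species, TRUE,
                    prob = c(0.25, 0.2, 0.55))
      hg <- ifelse(cls == "FFA", "none", sample(hgs, n_species, TRUE))
      fa1 <- sample(fas, n_species, TRUE, prob = wts)
      fa2 <- ifelse(cls == "diacyl", sample(fas, n_species, TRUE, prob = wts), "")
      p_up <- up_prob[hg]
      p_up[fa1 == "20:4" | fa2 == "20:4"] <- 0.1
      dir <- ifelse(stats::runif(n_species) < p_up, "up", "down")
      data.frame(
        species_id = sprintf("d%d_sp%03d", day, seq_len(n_species)),
        class = cls, headgroup = hg, fa1 = fa1, fa2 = fa2,
        direction = dir, day = day, stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, out)
}
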