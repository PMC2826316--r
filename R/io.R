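#' @name io
#' @title Readers and writers for the pipeline's plain-text formats
#' @description
#' All matrices travel as TSV with a header row of sample ids and feature
#' ids in the first column; spectra as two-column CSV (ppm, intensity) plus
#' a manifest TSV; term maps as GMT; fusion results as JSON. Every writer
#' and reader pair round-trips its canonical form.
NULL

#' Write / read a two-column spectrum CSV
#' @param ppm,intensity the spectrum.
#' @param path file path.
#' @rdname io
#' @export
write_spectrum_csv <- function(ppm, intensity, path) {
  utils::write.csv(data.frame(ppm = ppm, intensity = intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("ppm", "intensity") %in% names(df)))
    stop(path, ": expected columns 'ppm' and 'intensity'")
  df
}

#' Write a spectra_set as per-sample CSVs plus a manifest TSV
#' @param spectra a `spectra_set`.
#' @param dir output directory (created if needed).
#' @rdname io
#' @export
write_spectra_set <- function(spectra, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- rownames(spectra$intensities)
  files <- file.path(dir, paste0(ids, ".csv"))
  for (i in seq_along(ids))
    write_spectrum_csv(spectra$ppm, spectra$intensities[i, ], files[i])
  manifest <- cbind(spectra$design, file = basename(files))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a spectra directory written by write_spectra_set
#' @rdname io
#' @export
read_spectra_dir <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"))
  design <- manifest[, setdiff(names(manifest), "file"), drop = FALSE]
  validate_design(design)
  specs <- lapply(file.path(dir, manifest$file), read_spectrum_csv)
  ppm <- specs[[1]]$ppm
  for (s in specs) if (!isTRUE(all.equal(s$ppm, ppm)))
    stop("spectra in ", dir, " are not on a common ppm grid")
  intens <- do.call(rbind, lapply(specs, `[[`, "intensity"))
  rownames(intens) <- design$sample_id
  structure(list(ppm = ppm, intensities = intens, design = design),
            class = "spectra_set")
}

#' Write / read a numeric matrix as TSV (features x samples or any
#' orientation; first column = row ids, header = column ids)
#' @param m matrix.
#' @rdname io
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  suppress <- function(col, j) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is.na(col) & nzchar(col))
    if (length(bad))
      stop(sprintf("%s: non-numeric cell at row %d (id '%s'), column '%s'",
                   path, bad[1], ids[bad[1]], names(body)[j]))
    v
  }
  m <- vapply(seq_along(body), function(j) suppress(body[[j]], j),
              numeric(nrow(body)))
  m <- matrix(m, nrow = nrow(body),
              dimnames = list(ids, names(body)))
  m
}

#' Write / read a study design TSV
#' @param design a design data.frame.
#' @rdname io
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design[, c("sample_id", "dose", "day", "replicate")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_design_tsv <- function(path) {
  design <- utils::read.delim(path)
  validate_design(design)
  design
}

#' Read / write GMT term maps (term, description, members...)
#' @rdname io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop(sprintf("%s: line %d has fewer than 3 tab-separated fields", path, i))
    out[[parts[1]]] <- parts[-(1:2)]
  }
  out
}

#' @param term_map named list of member vectors.
#' @param descriptions optional named descriptions.
#' @rdname io
#' @export
write_gmt <- function(term_map, path, descriptions = NULL) {
  lines <- vapply(names(term_map), function(tm) {
    desc <- if (is.null(descriptions)) "na" else descriptions[[tm]]
    paste(c(tm, desc, term_map[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pathway-definition GMT whose metabolite members carry a "met:"
#' prefix; returns list(pathway -> list(genes, metabolites))
#' @rdname io
#' @export
read_pathway_gmt <- function(path) {
  raw <- read_gmt(path)
  lapply(raw, function(members) {
    is_met <- startsWith(members, "met:")
    list(genes = members[!is_met],
         metabolites = sub("^met:", "", members[is_met]))
  })
}

#' Write a fusion result as JSON (ranked loadings in a companion TSV)
#' @param result a `fusion_result`.
#' @rdname io
#' @export
write_fusion_json <- function(result, path) {
  out <- list(metabolite = result$metabolite,
              n_components = result$n_components,
              q2 = result$q2, permuted_q2 = result$permuted_q2,
              pass = result$pass, seed = result$seed,
              top = result$top)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read the lipid species CSV schema
#' @param species lipid species data.frame.
#' @rdname io
#' @export
write_lipid_csv <- function(species, path) {
  utils::write.csv(species, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_lipid_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  df$day <- as.numeric(df$day)
  df$fa2[is.na(df$fa2)] <- ""
  df
}

#' Write a bucket table as TSV with "lo-hi" interval column headers
#' @param table a [bucket_table()].
#' @rdname io
#' @export
write_bucket_table_tsv <- function(table, path) {
  write_matrix_tsv(table$values, path)
}

#' @param scheme the [bucket_scheme()] the table was built with (restores
#'   the interval bounds).
#' @param state normalization state to record.
#' @rdname io
#' @export
read_bucket_table_tsv <- function(path, scheme = NULL, state = "raw") {
  m <- read_matrix_tsv(path)
  parts <- strsplit(colnames(m), "-", fixed = TRUE)
  b <- data.frame(lo = as.numeric(vapply(parts, `[`, character(1), 1)),
                  hi = as.numeric(vapply(parts, `[`, character(1), 2)))
  bucket_table(m, b, state = state)
}
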