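## Readers/writers for the pipeline's text formats. Conventions (used
## everywhere): pixel coordinates are (col, row) with origin top-left; cM
## positions are plain real numbers; missing genotype token is "-"; missing
## trait values are empty cells. All writers produce files whose read-back
## reproduces the object exactly.

#' Write / read a two-genotype cross CSV
#'
#' Layout: row 1 holds `line` plus the marker names, row 2 the chromosome of
#' each marker, row 3 its cM position, and each following row one line's
#' `A`/`B` codes (`-` for missing).
#'
#' @param map Genetic map (`marker`, `chrom`, `pos`).
#' @param genotypes Character matrix lines x markers.
#' @param path Output path.
#' @return `path` invisibly (writer); list(`map`, `genotypes`) (reader).
#' @export
write_cross_csv <- function(map, genotypes, path) {
  map <- validate_genetic_map(map)
  stopifnot(is.matrix(genotypes), ncol(genotypes) == nrow(map))
  codes <- genotypes
  codes[is.na(codes)] <- "-"
  header <- c("line", map$marker)
  row2 <- c("", as.character(map$chrom))
  row3 <- c("", format(map$pos, trim = TRUE, digits = 15))
  body <- cbind(rownames(genotypes), codes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(paste(row2, collapse = ","), con)
  writeLines(paste(row3, collapse = ","), con)
  utils::write.table(body, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cross_csv
#' @export
read_cross_csv <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) < 3) stop("cross CSV must have marker/chromosome/cM header rows",
                          call. = FALSE)
  markers <- as.character(raw[1, -1])
  if (anyDuplicated(markers)) {
    stop("duplicate marker name: ", markers[duplicated(markers)][1], call. = FALSE)
  }
  chrom <- suppressWarnings(as.integer(raw[2, -1]))
  pos <- suppressWarnings(as.numeric(raw[3, -1]))
  if (anyNA(chrom) || anyNA(pos)) {
    stop("malformed chromosome or cM header row", call. = FALSE)
  }
  map <- data.frame(marker = markers, chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  for (k in unique(chrom)) {
    if (is.unsorted(pos[chrom == k])) {
      stop("non-monotone cM positions on chromosome ", k, call. = FALSE)
    }
  }
  map <- validate_genetic_map(map)
  if (nrow(raw) == 3) stop("no lines: genotype section is empty", call. = FALSE)
  body <- raw[-(1:3), , drop = FALSE]
  lines <- body[, 1]
  codes <- as.matrix(body[, -1, drop = FALSE])
  valid <- matrix(codes %in% c("A", "B", "-"), nrow = nrow(codes))
  bad <- which(!valid, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("unknown genotype code '%s' at line '%s', marker '%s'",
                 codes[bad[1, 1], bad[1, 2]], lines[bad[1, 1]],
                 markers[bad[1, 2]]), call. = FALSE)
  }
  codes[codes == "-"] <- NA_character_
  dimnames(codes) <- list(lines, markers)
  list(map = map, genotypes = codes)
}

#' Write / read a tidy trait CSV
#'
#' Columns `line`, `stage`, `trait`, `value`; empty cells denote missing
#' values. Stage labels can be validated against a declared design.
#'
#' @param pheno Tidy phenotype table.
#' @param path File path.
#' @param design Optional [study_design()]; read-back rejects stage labels
#'   outside `design$stages`.
#' @return `path` invisibly (writer); the table (reader).
#' @export
write_trait_csv <- function(pheno, path) {
  stopifnot(all(c("line", "stage", "trait", "value") %in% names(pheno)))
  utils::write.csv(pheno[, c("line", "stage", "trait", "value")], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trait_csv
#' @export
read_trait_csv <- function(path, design = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "stage", "trait", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trait CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("line", "stage", "trait")) df[[col]] <- as.character(df[[col]])
  df$value <- as.numeric(df$value)
  if (!is.null(design)) {
    design <- validate_study_design(design)
    bad <- setdiff(unique(df$stage), design$stages)
    if (length(bad)) {
      stop("stage label(s) outside the declared design: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  df[, need]
}

#' Write / read a QTL scan CSV
#'
#' Columns `trait`, `stage`, `chrom`, `pos`, `marker`, `lod`, `additive`,
#' `pve`, written sorted by `(trait, stage, chrom, pos)`.
#'
#' @param scans `data.frame` (a `qtl_scan` augmented with `trait`/`stage`,
#'   or several stacked).
#' @param path File path.
#' @return `path` invisibly (writer); the table (reader).
#' @export
write_scan_csv <- function(scans, path) {
  need <- c("trait", "stage", "chrom", "pos", "marker", "lod", "additive", "pve")
  missing_cols <- setdiff(need, names(scans))
  if (length(missing_cols)) {
    stop("scan table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  scans <- scans[order(scans$trait, scans$stage, scans$chrom, scans$pos), need]
  utils::write.csv(scans, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
read_scan_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(trait = "character", stage = "character",
                                       marker = "character"))
  need <- c("trait", "stage", "chrom", "pos", "marker", "lod", "additive", "pve")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("scan CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df[df$marker %in% "", "marker"] <- NA_character_
  df[, need]
}

#' Read a key-value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are
#' rejected. Values are parsed as numeric when possible, comma-separated
#' values become vectors.
#'
#' @param path File path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  known <- c("seed", "n_lines", "n_markers", "n_chromosomes", "total_cm",
             "stages", "n_perm", "alpha", "window", "step", "max_cofactors",
             "threshold_mode", "fixed_threshold", "height_fraction",
             "view_aggregate", "median_window", "morph_radius",
             "min_component_px", "yellow_b_threshold", "n_plants",
             "spread_min", "spread_max", "trait")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% known) stop("unknown config key: ", key, call. = FALSE)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) parts else num
  }
  out
}

## Small stable content hash (FNV-1a over the deparsed object) used to tag
## run manifests so reruns with the same configuration are recognizable.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647  # polynomial rolling hash
  sprintf("%08x", as.integer(h))
}
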