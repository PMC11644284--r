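## Peak calling, QTL naming, and consensus classification between
## conditional (increment) and unconditional (stage-wise) scans.

#' Conditional (increment) phenotypes between adjacent stages
#'
#' For a trait observed at consecutive stages, the conditional value of line
#' `i` at increment `k >= 2` is the exact difference
#' `dTk = T(stage_k) - T(stage_{k-1})`; `dT1` is the first-stage value
#' itself (the unconditional genetic effect of the first stage). Six weekly
#' stages yield the five increments dT2..dT6. A missing stage leaves the
#' affected increments `NA` for that line.
#'
#' @param pheno Tidy phenotype table (`line`, `stage`, `trait`, `value`).
#' @param trait Trait code to extract.
#' @param stages Ordered stage labels; defaults to order of appearance.
#' @return Tidy `data.frame`: `line`, `delta` (`"dT1"`, `"dT2"`, ...),
#'   `from_stage`, `to_stage`, `trait`, `value`.
#' @export
conditional_phenotypes <- function(pheno, trait, stages = NULL) {
  stopifnot(all(c("line", "stage", "trait", "value") %in% names(pheno)))
  ph <- pheno[pheno$trait == trait, ]
  if (nrow(ph) == 0) stop("trait not present in phenotype table", call. = FALSE)
  if (is.null(stages)) stages <- unique(ph$stage)
  lines <- unique(ph$line)
  wide <- matrix(NA_real_, length(lines), length(stages),
                 dimnames = list(lines, stages))
  wide[cbind(match(ph$line, lines), match(ph$stage, stages))] <- ph$value
  out <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    value <- if (k == 1) wide[, 1] else wide[, k] - wide[, k - 1]
    out[[k]] <- data.frame(line = lines, delta = paste0("dT", k),
                           from_stage = if (k == 1) NA_character_ else stages[k - 1],
                           to_stage = stages[k], trait = trait, value = value,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call QTL peaks from a scan
#'
#' Local maxima above the threshold are reported iteratively: the highest
#' remaining position on each chromosome becomes a peak and its support
#' interval is the contiguous region within `lod_drop` LOD of the peak
#' (bounded outward by the flanking markers). Before the next peak is
#' taken, candidates within `min_peak_sep` cM of the accepted interval are
#' suppressed, as are candidates with no real valley between themselves and
#' an accepted peak (the LOD must dip by at least `peak_drop` below the
#' candidate on the path between them) — otherwise the linkage shoulder of
#' one strong QTL would be reported as a second QTL.
#' Names follow the "q + trait code + chromosome" convention with
#' "-1", "-2" suffixes for additional peaks on the same chromosome (ordered
#' by position) and a "_stage" suffix; the parent contributing the
#' trait-increasing allele is Milyang23 when the additive effect is
#' positive, Giho otherwise.
#'
#' @param scan A `qtl_scan` from [cim_scan()].
#' @param threshold LOD threshold.
#' @param map Genetic map (for flanking markers).
#' @param trait Trait code used in names (e.g. `"TA"`).
#' @param stage Stage label appended as `"_stage"`; `NA` to omit.
#' @param prefix Name prefix (`"q"` unconditional, `"cq"` conditional).
#' @param lod_drop Support-interval drop (default 1 LOD).
#' @param min_peak_sep Minimum separation between distinct peaks, cM.
#' @param peak_drop Required LOD dip between distinct peaks on one
#'   chromosome.
#' @return `data.frame` of peaks (possibly 0 rows): `name`, `trait`,
#'   `stage`, `chrom`, `pos`, `lod`, `additive`, `pve`, `parent`, `ci_lo`,
#'   `ci_hi`, `flank_lo`, `flank_hi`.
#' @export
call_peaks <- function(scan, threshold, map, trait = "TA", stage = NA,
                       prefix = "q", lod_drop = 1, min_peak_sep = 20,
                       peak_drop = 2) {
  map <- validate_genetic_map(map)
  empty <- data.frame(name = character(0), trait = character(0),
                      stage = character(0), chrom = integer(0), pos = numeric(0),
                      lod = numeric(0), additive = numeric(0), pve = numeric(0),
                      parent = character(0), ci_lo = numeric(0), ci_hi = numeric(0),
                      flank_lo = character(0), flank_hi = character(0),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (k in unique(scan$chrom)) {
    sc <- scan[scan$chrom == k, ]
    sc <- sc[order(sc$pos), ]
    avail <- sc$lod >= threshold
    while (any(avail)) {
      i <- which(avail)[which.max(sc$lod[avail])]
      peak_lod <- sc$lod[i]
      ## contiguous support region within lod_drop of the peak
      lo <- i; while (lo > 1 && sc$lod[lo - 1] >= peak_lod - lod_drop) lo <- lo - 1
      hi <- i; while (hi < nrow(sc) && sc$lod[hi + 1] >= peak_lod - lod_drop) hi <- hi + 1
      ci <- c(sc$pos[lo], sc$pos[hi])
      mk <- map[map$chrom == k, ]
      below <- mk$marker[mk$pos <= ci[1]]
      above <- mk$marker[mk$pos >= ci[2]]
      rows[[length(rows) + 1L]] <- data.frame(
        name = NA_character_, trait = trait,
        stage = if (is.na(stage)) NA_character_ else as.character(stage),
        chrom = k, pos = sc$pos[i], lod = peak_lod,
        additive = sc$additive[i], pve = sc$pve[i],
        parent = if (sc$additive[i] > 0) "Milyang23" else "Giho",
        ci_lo = ci[1], ci_hi = ci[2],
        flank_lo = if (length(below)) below[length(below)] else mk$marker[1],
        flank_hi = if (length(above)) above[1] else mk$marker[nrow(mk)],
        stringsAsFactors = FALSE)
      avail <- avail & (sc$pos < ci[1] - min_peak_sep | sc$pos > ci[2] + min_peak_sep)
      ## suppress shoulders: a further candidate needs a genuine valley
      ## (LOD dip >= peak_drop below it) between itself and this peak
      if (any(avail)) {
        for (j in which(avail)) {
          path <- sc$lod[min(i, j):max(i, j)]
          if (min(path) > sc$lod[j] - peak_drop) avail[j] <- FALSE
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  peaks <- do.call(rbind, rows)
  peaks <- peaks[order(peaks$chrom, peaks$pos), ]
  rownames(peaks) <- NULL
  for (k in unique(peaks$chrom)) {
    j <- which(peaks$chrom == k)
    base <- paste0(prefix, trait, k)
    suffix <- c("", paste0("-", seq_len(max(0, length(j) - 1))))
    nm <- paste0(base, suffix[seq_along(j)])
    if (!is.na(stage)) nm <- paste0(nm, "_", stage)
    peaks$name[j] <- nm
  }
  peaks
}

#' Classify conditional QTLs as consensus or non-consensus
#'
#' A conditional peak is a consensus QTL when its support interval shares at
#' least `min_overlap` cM with the interval of an unconditional peak for the
#' same trait on the same chromosome. Overlaps with unconditional peaks of
#' *other* traits do not make a peak consensus but are recorded, along with
#' whether the additive effects point in the same direction.
#'
#' @param conditional_peaks Peaks from a conditional (increment) scan.
#' @param unconditional_peaks Peaks from stage-wise scans (may mix traits;
#'   rows with `trait == trait` drive the classification).
#' @param trait Trait code of interest.
#' @param min_overlap Minimum shared interval length in cM.
#' @return `conditional_peaks` with added columns `class`
#'   (`"conditional-consensus"` / `"conditional-non-consensus"`),
#'   `overlaps` (comma-separated names of overlapping unconditional QTLs of
#'   the same trait), `same_direction` (logical, w.r.t. the first same-trait
#'   overlap), and `other_trait_overlaps`.
#' @export
classify_consensus <- function(conditional_peaks, unconditional_peaks,
                               trait = "TA", min_overlap = 1) {
  cp <- conditional_peaks
  if (nrow(cp) == 0) {
    cp$class <- character(0); cp$overlaps <- character(0)
    cp$same_direction <- logical(0); cp$other_trait_overlaps <- character(0)
    return(cp)
  }
  up <- unconditional_peaks
  same <- up[up$trait == trait, , drop = FALSE]
  other <- up[up$trait != trait, , drop = FALSE]
  overlap_len <- function(a_lo, a_hi, b_lo, b_hi) {
    pmin(a_hi, b_hi) - pmax(a_lo, b_lo)
  }
  cp$class <- NA_character_; cp$overlaps <- NA_character_
  cp$same_direction <- NA; cp$other_trait_overlaps <- NA_character_
  for (i in seq_len(nrow(cp))) {
    hit <- which(same$chrom == cp$chrom[i] &
                   overlap_len(cp$ci_lo[i], cp$ci_hi[i], same$ci_lo, same$ci_hi)
                 >= min_overlap)
    if (length(hit)) {
      cp$class[i] <- "conditional-consensus"
      cp$overlaps[i] <- paste(same$name[hit], collapse = ",")
      cp$same_direction[i] <- sign(cp$additive[i]) == sign(same$additive[hit[1]])
    } else {
      cp$class[i] <- "conditional-non-consensus"
    }
    ohit <- which(other$chrom == cp$chrom[i] &
                    overlap_len(cp$ci_lo[i], cp$ci_hi[i], other$ci_lo, other$ci_hi)
                  >= min_overlap)
    if (length(ohit)) {
      cp$other_trait_overlaps[i] <- paste(other$name[ohit], collapse = ",")
    }
  }
  cp
}
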