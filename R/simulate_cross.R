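## Synthetic RIL population: genetic map, genotypes, phenotypes.
##
## Emulates the Milyang23 x Giho RIL design: 162 fully inbred lines genotyped
## at 466 markers over 12 chromosomes spanning 1697 cM (Kosambi). Genotype
## codes are "A" (Milyang23 allele) and "B" (Giho allele); lines are fully
## homozygous (F25+), so each chromosome is a two-state Markov chain with
## transition probability R = 2r/(1+2r) per marker interval.

#' Build a synthetic genetic map
#'
#' Markers are spread at equal spacing within chromosomes; chromosome sizes
#' and marker counts are split as evenly as possible. Defaults mirror the
#' published map scale (466 markers, 12 chromosomes, 1697 cM total); the real
#' marker spacing distribution is unknown, so equal spacing is an explicit
#' simplification.
#'
#' @param n_markers Total number of markers.
#' @param n_chromosomes Number of chromosomes.
#' @param total_cm Total map length in cM (summed over chromosomes).
#' @return A `data.frame` with columns `marker`, `chrom` (integer),
#'   `pos` (cM from the top of the chromosome).
#' @export
make_genetic_map <- function(n_markers = 466, n_chromosomes = 12, total_cm = 1697) {
  stop_if_not_scalar_number(n_markers, "n_markers", lower = 2)
  stop_if_not_scalar_number(n_chromosomes, "n_chromosomes", lower = 1)
  stop_if_not_scalar_number(total_cm, "total_cm", lower = 0)
  per <- rep(floor(n_markers / n_chromosomes), n_chromosomes)
  extra <- n_markers - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  chrom_len <- total_cm / n_chromosomes
  rows <- lapply(seq_len(n_chromosomes), function(k) {
    n <- per[k]
    pos <- if (n == 1) 0 else seq(0, chrom_len, length.out = n)
    data.frame(
      marker = sprintf("M%02d_%03d", k, seq_len(n)),
      chrom = k,
      pos = pos,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  validate_genetic_map(map)
}

#' @keywords internal
validate_genetic_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("marker", "chrom", "pos") %in% names(map)))
  if (anyDuplicated(map$marker)) stop("duplicate marker names in map", call. = FALSE)
  for (k in unique(map$chrom)) {
    p <- map$pos[map$chrom == k]
    if (is.unsorted(p)) stop(sprintf("positions on chromosome %s not non-decreasing", k),
                             call. = FALSE)
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Simulate fully inbred RIL genotypes
#'
#' Each line's chromosome is an independent two-state Markov chain over the
#' ordered markers: the first marker is "A" or "B" with probability 1/2, and
#' adjacent markers recombine with probability `R = 2r/(1+2r)`, where the
#' meiotic `r` comes from the inverse Kosambi function applied to the marker
#' interval. Chromosomes and lines are independent; lines carry no residual
#' heterozygosity. A configurable fraction of calls can be masked as missing.
#'
#' @param map Genetic map from [make_genetic_map()] (or same columns).
#' @param n_lines Number of lines (>= 2).
#' @param seed Integer seed.
#' @param missing_rate Fraction of genotype calls set to `NA` (default 0).
#' @return Character matrix (`n_lines` x markers) of `"A"`/`"B"` codes,
#'   with `NA` for missing; `dimnames` are line IDs and marker names.
#' @export
simulate_ril_genotypes <- function(map, n_lines, seed = 1, missing_rate = 0) {
  map <- validate_genetic_map(map)
  stop_if_not_scalar_number(n_lines, "n_lines", lower = 2)
  stop_if_not_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 0.95)
  with_seed(seed, {
    geno <- matrix(NA_character_, nrow = n_lines, ncol = nrow(map),
                   dimnames = list(sprintf("RIL%03d", seq_len(n_lines)), map$marker))
    for (k in unique(map$chrom)) {
      idx <- which(map$chrom == k)
      Rstep <- ril_recombination(diff(map$pos[idx]))
      state <- stats::runif(n_lines) < 0.5  # TRUE = A
      geno[, idx[1]] <- ifelse(state, "A", "B")
      if (length(idx) > 1) {
        for (j in seq_along(Rstep)) {
          flip <- stats::runif(n_lines) < Rstep[j]
          state <- xor(state, flip)
          geno[, idx[j + 1]] <- ifelse(state, "A", "B")
        }
      }
    }
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(length(geno)) < missing_rate, nrow = n_lines)
      geno[drop] <- NA_character_
    }
    geno
  })
}

#' Additive effect size that yields a target PVE
#'
#' For a biallelic locus coded +1/-1 with allele frequency 1/2 in a RIL
#' population, the genetic variance is `a^2`, so a QTL explaining a fraction
#' `pve` of the phenotypic variance against residual s.d. `sigma` has
#' `a = sigma * sqrt(pve / (1 - pve))`.
#'
#' @param pve Target fraction of phenotypic variance explained, in (0, 1).
#' @param sigma Residual standard deviation.
#' @return Additive effect `a`.
#' @export
additive_effect_for_pve <- function(pve, sigma) {
  stop_if_not_scalar_number(pve, "pve", lower = 1e-9, upper = 1 - 1e-9)
  stop_if_not_scalar_number(sigma, "sigma", lower = 0)
  sigma * sqrt(pve / (1 - pve))
}

#' Simulate a RIL cross with planted QTL effects and stage-wise phenotypes
#'
#' Generates genotypes with [simulate_ril_genotypes()] (the planted QTL loci
#' are simulated on the same Markov chain as the markers, so marker-QTL
#' linkage is exact) and phenotypes
#' `y[line, stage] = mu[stage] + sum_q a_q * x_q + eps`,
#' with `x_q = +1` for the Milyang23 ("A") allele and `-1` for Giho ("B"),
#' and `eps ~ N(0, sigma[stage]^2)` independent across lines and stages.
#' A QTL row with `stage = NA` acts at every stage; otherwise only at the
#' named stage.
#'
#' @param map Genetic map.
#' @param n_lines Number of lines.
#' @param qtls `data.frame` with columns `chrom`, `pos`, `additive`, and
#'   optionally `trait` (default `"TA"`) and `stage` (default `NA` = all
#'   stages). May be `NULL` for a pure-noise trait.
#' @param stages Character vector of ordered stage labels.
#' @param stage_means Numeric vector of per-stage baselines (recycled).
#' @param sigma Per-stage residual s.d. (recycled); must be `>= 0`.
#' @param trait Trait code used in the phenotype table.
#' @param seed Integer seed.
#' @param missing_rate Passed to [simulate_ril_genotypes()].
#' @return A list of class `sim_cross`: `map`, `genotypes`, `qtls` (with a
#'   `realized_pve` column per stage at which each QTL acts), `qtl_codes`
#'   (lines x QTLs, +1/-1), `phenotypes` (tidy `line`, `stage`, `trait`,
#'   `value`), `stages`, `sigma`, `seed`.
#' @export
simulate_cross <- function(map, n_lines = 162, qtls = NULL,
                           stages = paste0(4:9, "W"),
                           stage_means = seq(15, 30, length.out = length(stages)),
                           sigma = 3, trait = "TA", seed = 1,
                           missing_rate = 0) {
  map <- validate_genetic_map(map)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (anyDuplicated(stages)) stop("stage labels must be unique", call. = FALSE)
  stage_means <- rep_len(stage_means, length(stages))
  sigma <- rep_len(sigma, length(stages))
  if (!is.null(qtls)) {
    stopifnot(is.data.frame(qtls), all(c("chrom", "pos", "additive") %in% names(qtls)))
    if (is.null(qtls$trait)) qtls$trait <- trait
    if (is.null(qtls$stage)) qtls$stage <- NA_character_
    chrom_ends <- tapply(map$pos, map$chrom, max)
    for (i in seq_len(nrow(qtls))) {
      if (!qtls$chrom[i] %in% map$chrom ||
          qtls$pos[i] < 0 || qtls$pos[i] > chrom_ends[[as.character(qtls$chrom[i])]]) {
        stop(sprintf("planted QTL %d does not lie on the map", i), call. = FALSE)
      }
      if (!is.na(qtls$stage[i]) && !qtls$stage[i] %in% stages) {
        stop(sprintf("planted QTL %d references unknown stage '%s'", i, qtls$stage[i]),
             call. = FALSE)
      }
    }
  }

  ## simulate markers and QTL positions on one chain so linkage is exact
  aug <- map[, c("marker", "chrom", "pos")]
  qtl_names <- character(0)
  if (!is.null(qtls) && nrow(qtls) > 0) {
    qtl_names <- sprintf("QTL%02d", seq_len(nrow(qtls)))
    aug <- rbind(aug, data.frame(marker = qtl_names, chrom = qtls$chrom,
                                 pos = qtls$pos, stringsAsFactors = FALSE))
    aug <- aug[order(aug$chrom, aug$pos), ]
  }
  aug <- validate_genetic_map(aug)
  geno_aug <- simulate_ril_genotypes(aug, n_lines, seed = seed, missing_rate = 0)
  genotypes <- geno_aug[, map$marker, drop = FALSE]
  qtl_codes <- NULL
  if (length(qtl_names)) {
    qtl_codes <- ifelse(geno_aug[, qtl_names, drop = FALSE] == "A", 1, -1)
    colnames(qtl_codes) <- qtl_names
  }
  if (missing_rate > 0) {
    genotypes <- with_seed(seed + 1L, {
      drop <- matrix(stats::runif(length(genotypes)) < missing_rate,
                     nrow = nrow(genotypes))
      genotypes[drop] <- NA_character_
      genotypes
    })
  }

  lines <- rownames(genotypes)
  pheno <- with_seed(seed + 2L, {
    out <- vector("list", length(stages))
    for (s in seq_along(stages)) {
      y <- rep(stage_means[s], n_lines)
      if (!is.null(qtls) && nrow(qtls) > 0) {
        for (q in seq_len(nrow(qtls))) {
          if (is.na(qtls$stage[q]) || qtls$stage[q] == stages[s]) {
            y <- y + qtls$additive[q] * qtl_codes[, q]
          }
        }
      }
      y <- y + stats::rnorm(n_lines, 0, sigma[s])
      out[[s]] <- data.frame(line = lines, stage = stages[s], trait = trait,
                             value = y, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  rownames(pheno) <- NULL

  if (!is.null(qtls) && nrow(qtls) > 0) {
    qtls$realized_pve <- vapply(seq_len(nrow(qtls)), function(q) {
      st <- if (is.na(qtls$stage[q])) stages else qtls$stage[q]
      mean(vapply(st, function(s) {
        y <- pheno$value[pheno$stage == s]
        g <- qtls$additive[q] * qtl_codes[, q]
        stats::var(g) / stats::var(y)
      }, numeric(1)))
    }, numeric(1))
  }

  structure(list(map = map, genotypes = genotypes, qtls = qtls,
                 qtl_codes = qtl_codes, phenotypes = pheno, stages = stages,
                 sigma = sigma, seed = seed),
            class = "sim_cross")
}

#' Enumerate the imaging design
#'
#' Number of image records implied by a fully crossed design:
#' `(n_ril + n_parents) * reps_per_line * n view angles * n stages`.
#' The published design (162 RILs + 2 parents, 6 replicates, 3 view angles,
#' 6 weekly stages) enumerates to 17,712 images.
#'
#' @param design A list/`study_design` with fields `n_ril`, `n_parents`,
#'   `reps_per_line`, `view_angles`, `stages`.
#' @return Integer count of image records.
#' @export
enumerate_imaging_design <- function(design) {
  design <- validate_study_design(design)
  as.integer((design$n_ril + design$n_parents) * design$reps_per_line *
               length(design$view_angles) * length(design$stages))
}

#' Describe an imaging study design
#'
#' @param n_ril Number of RILs.
#' @param n_parents Number of parental lines.
#' @param reps_per_line Replicates per line.
#' @param view_angles Camera view angles in degrees.
#' @param stages Ordered, unique stage labels (e.g. `"4W" ... "9W"`).
#' @return A `study_design` list.
#' @export
study_design <- function(n_ril = 162, n_parents = 2, reps_per_line = 6,
                         view_angles = c(0, 120, 240),
                         stages = paste0(4:9, "W")) {
  validate_study_design(list(n_ril = n_ril, n_parents = n_parents,
                             reps_per_line = reps_per_line,
                             view_angles = view_angles, stages = stages))
}

#' @keywords internal
validate_study_design <- function(design) {
  stopifnot(is.list(design),
            all(c("n_ril", "n_parents", "reps_per_line", "view_angles", "stages")
                %in% names(design)))
  for (f in c("n_ril", "n_parents", "reps_per_line")) {
    stop_if_not_scalar_number(design[[f]], f, lower = 0)
  }
  if (length(design$view_angles) < 1 || length(design$stages) < 1) {
    stop("design needs at least one view angle and one stage", call. = FALSE)
  }
  if (anyDuplicated(design$stages)) stop("stage labels must be unique", call. = FALSE)
  class(design) <- "study_design"
  design
}
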