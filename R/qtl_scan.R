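## Composite interval mapping for fully inbred RIL populations.
##
## Genotype probabilities come from a two-state Markov chain along each
## chromosome with transition probability R = 2r/(1+2r) per interval
## (r from the inverse Kosambi function); missing marker calls are
## marginalized by forward-backward smoothing. The scan is Haley-Knott
## regression of the phenotype on the expected genotype code 2*P(A)-1 at
## each grid position, with selected background markers as cofactors except
## inside a window around the test position.

#' Genotype probabilities on an evaluation grid
#'
#' Computes `P(genotype = A)` for every line at every marker and at pseudo
#' positions spaced `step` cM apart. At a marker with an observed call the
#' probability is exactly 0 or 1; missing calls are marginalized via the
#' Markov model.
#'
#' @param map Genetic map (`marker`, `chrom`, `pos`).
#' @param genotypes Character matrix lines x markers of `"A"`/`"B"`/`NA`.
#' @param step Grid spacing in cM; `NULL` evaluates at markers only.
#' @return A `geno_prob` list: `positions` (`data.frame` with `chrom`, `pos`,
#'   `marker` — `NA` for pseudo positions) and `prob` (lines x positions
#'   matrix of `P(A)`).
#' @export
genotype_probabilities <- function(map, genotypes, step = 1) {
  map <- validate_genetic_map(map)
  stopifnot(is.matrix(genotypes), ncol(genotypes) == nrow(map))
  if (!all(genotypes %in% c("A", "B", NA_character_))) {
    stop("genotype codes must be 'A', 'B' or NA", call. = FALSE)
  }
  n <- nrow(genotypes)
  pos_list <- list(); prob_list <- list()
  for (k in unique(map$chrom)) {
    midx <- which(map$chrom == k)
    mpos <- map$pos[midx]
    if (is.null(step)) {
      loci <- data.frame(pos = mpos, marker = map$marker[midx])
    } else {
      grid <- seq(min(mpos), max(mpos), by = step)
      allpos <- sort(unique(round(c(mpos, grid), 10)))
      marker_at <- rep(NA_character_, length(allpos))
      marker_at[match(round(mpos, 10), allpos)] <- map$marker[midx]
      loci <- data.frame(pos = allpos, marker = marker_at)
    }
    L <- nrow(loci)
    ## emissions: n x 2 per locus (columns A, B)
    emis <- vector("list", L)
    for (j in seq_len(L)) {
      if (is.na(loci$marker[j])) {
        emis[[j]] <- matrix(1, n, 2)
      } else {
        g <- genotypes[, loci$marker[j]]
        e <- matrix(1, n, 2)
        e[which(g == "A"), 2] <- 0
        e[which(g == "B"), 1] <- 0
        emis[[j]] <- e
      }
    }
    R <- ril_recombination(diff(loci$pos))
    ## forward
    fwd <- vector("list", L)
    f <- emis[[1]] * 0.5
    fwd[[1]] <- f / rowSums(f)
    for (j in seq_len(L - 1)) {
      Tm <- matrix(c(1 - R[j], R[j], R[j], 1 - R[j]), 2, 2)
      f <- (fwd[[j]] %*% Tm) * emis[[j + 1]]
      fwd[[j + 1]] <- f / rowSums(f)
    }
    ## backward + posterior
    prob_k <- matrix(NA_real_, n, L)
    b <- matrix(1, n, 2)
    post <- fwd[[L]]
    prob_k[, L] <- post[, 1]
    for (j in seq(L - 1, by = -1, length.out = L - 1)) {
      Tm <- matrix(c(1 - R[j], R[j], R[j], 1 - R[j]), 2, 2)
      b <- (b * emis[[j + 1]]) %*% Tm  # symmetric transition
      b <- b / rowSums(b)
      post <- fwd[[j]] * b
      prob_k[, j] <- post[, 1] / rowSums(post)
    }
    pos_list[[length(pos_list) + 1L]] <-
      data.frame(chrom = k, pos = loci$pos, marker = loci$marker,
                 stringsAsFactors = FALSE)
    prob_list[[length(prob_list) + 1L]] <- prob_k
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  structure(list(positions = positions,
                 prob = do.call(cbind, prob_list),
                 lines = rownames(genotypes)),
            class = "geno_prob")
}

#' Coded marker genotypes (+1 Milyang23 / -1 Giho)
#'
#' Missing calls are replaced by their conditional expectation
#' `2 * P(A) - 1` from the Markov model.
#'
#' @param map Genetic map.
#' @param genotypes Character genotype matrix.
#' @return Numeric lines x markers matrix.
#' @export
coded_genotypes <- function(map, genotypes) {
  if (!anyNA(genotypes)) {
    x <- ifelse(genotypes == "A", 1, -1)
    dimnames(x) <- dimnames(genotypes)
    return(x)
  }
  pr <- genotype_probabilities(map, genotypes, step = NULL)
  x <- 2 * pr$prob - 1
  colnames(x) <- pr$positions$marker
  rownames(x) <- rownames(genotypes)
  x
}

#' LOD score from residual sums of squares
#'
#' `LOD = (n/2) * log10(rss_null / rss_full)`. If `rss_full > rss_null`
#' (numerically possible with forced model terms) the LOD is floored at 0
#' with a warning.
#'
#' @param n Number of observations (> 2).
#' @param rss_null,rss_full Residual sums of squares (> 0).
#' @return LOD score >= 0.
#' @export
lod_from_rss <- function(n, rss_null, rss_full) {
  stop_if_not_scalar_number(n, "n", lower = 3)
  if (any(rss_null <= 0) || any(rss_full <= 0)) {
    stop("residual sums of squares must be > 0", call. = FALSE)
  }
  lod <- (n / 2) * log10(rss_null / rss_full)
  if (any(lod < 0)) {
    warning("rss_full > rss_null; LOD floored at 0", call. = FALSE)
    lod <- pmax(lod, 0)
  }
  lod
}

## Core Haley-Knott machinery shared by the scan and the permutation
## threshold. Y may hold many phenotype columns (permutations); returns
## per-position LOD for each column plus additive effects and PVE for the
## first column.
scan_core <- function(probs, Y, cof_x = NULL, cof_chrom = NULL, cof_pos = NULL,
                      window = 10) {
  X <- 2 * probs$prob - 1
  pos <- probs$positions
  n <- nrow(Y); P <- ncol(X); m <- ncol(Y)
  lod <- matrix(0, P, m)
  additive <- numeric(P)
  pve <- numeric(P)
  tss1 <- sum((Y[, 1] - mean(Y[, 1]))^2)
  n_cof <- if (is.null(cof_x)) 0L else ncol(cof_x)

  ## group positions by identical active-cofactor sets
  if (n_cof == 0L) {
    groups <- list(list(active = integer(0), idx = seq_len(P)))
  } else {
    keys <- vapply(seq_len(P), function(j) {
      act <- which(cof_chrom != pos$chrom[j] | abs(cof_pos - pos$pos[j]) > window)
      paste(act, collapse = ",")
    }, character(1))
    groups <- lapply(split(seq_len(P), keys), function(idx) {
      j <- idx[1]
      list(active = which(cof_chrom != pos$chrom[j] |
                            abs(cof_pos - pos$pos[j]) > window), idx = idx)
    })
  }

  for (g in groups) {
    Z <- cbind(rep(1, n), if (length(g$active)) cof_x[, g$active, drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      warning("collinear cofactors dropped from the scan model", call. = FALSE)
    }
    Yr <- qr.resid(qz, Y)
    Xr <- qr.resid(qz, X[, g$idx, drop = FALSE])
    rss0 <- colSums(Yr^2)
    xtx <- colSums(Xr^2)
    xty <- crossprod(Xr, Yr)                 # |idx| x m
    ok <- xtx > 1e-10 & rss0[1] > 1e-12
    r2 <- (xty^2) / outer(pmax(xtx, 1e-10), pmax(rss0, 1e-12))
    r2 <- pmin(r2, 1 - 1e-12)
    lod[g$idx, ] <- -(n / 2) * log10(1 - r2)
    if (any(!ok)) lod[g$idx[!ok], ] <- 0
    additive[g$idx] <- ifelse(xtx > 1e-10, xty[, 1] / xtx, 0)
    pve[g$idx] <- (rss0[1] * r2[, 1]) / tss1
  }
  list(lod = lod, additive = additive, pve = pve)
}

#' Composite interval mapping scan
#'
#' Haley-Knott regression of the phenotype on the expected genotype code at
#' every grid position, with the supplied cofactor markers in the model
#' except when they lie within `window` cM of the test position on the same
#' chromosome. The LOD compares against the cofactor-only null; the additive
#' effect is half the fitted genotype contrast (positive = Milyang23 allele
#' increases the trait); PVE is the partial R-squared at the position
#' against the total phenotypic variance.
#'
#' @param map Genetic map.
#' @param genotypes Character genotype matrix (lines x markers).
#' @param phenotype Numeric vector, one value per line, in row order of
#'   `genotypes`.
#' @param cofactors Character vector of cofactor marker names (possibly
#'   empty; the scan then degenerates to simple interval mapping).
#' @param window Exclusion window around the test position, cM.
#' @param step Grid spacing in cM.
#' @param probs Optional precomputed [genotype_probabilities()] (must match
#'   `map`/`genotypes`/`step`).
#' @return A `qtl_scan` `data.frame`: `chrom`, `pos`, `marker`, `lod`,
#'   `additive`, `pve`; attribute `cofactors`.
#' @export
cim_scan <- function(map, genotypes, phenotype, cofactors = character(0),
                     window = 10, step = 1, probs = NULL) {
  map <- validate_genetic_map(map)
  stopifnot(length(phenotype) == nrow(genotypes), !anyNA(phenotype))
  if (is.null(probs)) probs <- genotype_probabilities(map, genotypes, step = step)
  cof <- prepare_cofactors(map, genotypes, cofactors)
  res <- scan_core(probs, matrix(phenotype, ncol = 1),
                   cof$x, cof$chrom, cof$pos, window = window)
  out <- data.frame(chrom = probs$positions$chrom, pos = probs$positions$pos,
                    marker = probs$positions$marker,
                    lod = res$lod[, 1], additive = res$additive, pve = res$pve,
                    stringsAsFactors = FALSE)
  attr(out, "cofactors") <- cofactors
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' @keywords internal
prepare_cofactors <- function(map, genotypes, cofactors) {
  if (length(cofactors) == 0) return(list(x = NULL, chrom = NULL, pos = NULL))
  bad <- setdiff(cofactors, map$marker)
  if (length(bad)) stop("unknown cofactor marker(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  coded <- coded_genotypes(map, genotypes)[, cofactors, drop = FALSE]
  i <- match(cofactors, map$marker)
  list(x = coded, chrom = map$chrom[i], pos = map$pos[i])
}

#' Forward stepwise cofactor selection
#'
#' Markers enter by largest partial F against the current model. Because the
#' best of several hundred correlated candidates is examined at each step,
#' the entry p-value is Bonferroni-adjusted over the remaining candidates;
#' selection stops when the adjusted p exceeds `entry_alpha` or
#' `max_cofactors` is reached. Markers within `window` cM of an already
#' selected marker on the same chromosome are not eligible.
#'
#' @param map Genetic map.
#' @param genotypes Character genotype matrix.
#' @param phenotype Numeric vector, one value per line.
#' @param max_cofactors Maximum number of cofactors (0 gives simple interval
#'   mapping).
#' @param window Exclusion window around selected markers, cM.
#' @param entry_alpha Entry threshold on the adjusted p-value.
#' @return Character vector of selected marker names (possibly empty).
#' @export
select_cofactors <- function(map, genotypes, phenotype, max_cofactors = 5,
                             window = 10, entry_alpha = 0.05) {
  map <- validate_genetic_map(map)
  stopifnot(length(phenotype) == nrow(genotypes))
  if (max_cofactors < 1) return(character(0))
  M <- coded_genotypes(map, genotypes)
  n <- length(phenotype)
  selected <- character(0)
  eligible <- rep(TRUE, nrow(map))
  Z <- matrix(1, n, 1)
  repeat {
    qz <- qr(Z)
    yr <- qr.resid(qz, phenotype)
    rss0 <- sum(yr^2)
    if (rss0 < 1e-12 || !any(eligible)) break
    Mr <- qr.resid(qz, M[, eligible, drop = FALSE])
    xtx <- colSums(Mr^2)
    r2 <- ifelse(xtx > 1e-10, (crossprod(Mr, yr)[, 1]^2) / (xtx * rss0), 0)
    df2 <- n - ncol(Z) - 1
    if (df2 < 1) break
    Fstat <- df2 * r2 / (1 - pmin(r2, 1 - 1e-12))
    best <- which.max(Fstat)
    p_adj <- min(1, stats::pf(Fstat[best], 1, df2, lower.tail = FALSE) * sum(eligible))
    if (p_adj > entry_alpha) break
    mk <- which(eligible)[best]
    selected <- c(selected, map$marker[mk])
    Z <- cbind(Z, M[, mk])
    eligible <- eligible & !(map$chrom == map$chrom[mk] &
                               abs(map$pos - map$pos[mk]) <= window)
    if (length(selected) >= max_cofactors) break
  }
  selected
}

#' Permutation LOD threshold
#'
#' Phenotype values are permuted across lines `n_perm` times; each permuted
#' vector is scanned genome-wide (with the same cofactors and window as the
#' real scan) and the threshold is the empirical `(1 - alpha)` quantile of
#' the genome-wide maximum LOD. Deterministic given `seed`.
#'
#' @inheritParams cim_scan
#' @param n_perm Number of permutations (>= 100; the published analysis used
#'   1000).
#' @param alpha Genome-wide significance level.
#' @param seed Integer seed.
#' @return LOD threshold with attribute `max_lods` (the permutation maxima).
#' @export
permutation_threshold <- function(map, genotypes, phenotype, n_perm = 1000,
                                  alpha = 0.05, seed = 1,
                                  cofactors = character(0), window = 10,
                                  step = 1, probs = NULL) {
  stop_if_not_scalar_number(n_perm, "n_perm", lower = 100)
  stop_if_not_scalar_number(alpha, "alpha", lower = 1e-6, upper = 0.5)
  if (is.null(probs)) probs <- genotype_probabilities(map, genotypes, step = step)
  n <- length(phenotype)
  Y <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) phenotype[sample.int(n)], numeric(n))
  })
  cof <- prepare_cofactors(map, genotypes, cofactors)
  res <- scan_core(probs, Y, cof$x, cof$chrom, cof$pos, window = window)
  max_lods <- apply(res$lod, 2, max)
  thr <- unname(stats::quantile(max_lods, 1 - alpha))
  structure(thr, max_lods = max_lods)
}
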