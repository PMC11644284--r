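## Descriptive statistics: Pearson correlation matrix across traits,
## parental comparisons, and stage-wise distribution summaries.

#' Pairwise Pearson correlation matrix with p-values
#'
#' Correlations are computed on line-level values (one row per line; average
#' replicates and camera views before calling this). Each pair uses its
#' complete observations; a pair with fewer than 3 complete observations or
#' a constant trait is reported as `NA`.
#'
#' @param trait_table `data.frame` or matrix, lines x traits (numeric).
#' @return A `correlation_matrix` list: `r`, `p` (two-sided), `n` (complete
#'   pairs), all traits x traits.
#' @export
correlation_matrix <- function(trait_table) {
  m <- as.matrix(trait_table)
  stopifnot(is.numeric(m))
  traits <- colnames(m)
  k <- ncol(m)
  r <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  p <- r
  n <- matrix(0L, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- stats::complete.cases(m[, i], m[, j])
      n[i, j] <- n[j, i] <- sum(ok)
      if (i == j) {
        if (sum(ok) >= 1 && stats::sd(m[ok, i]) > 0) { r[i, j] <- 1; p[i, j] <- 0 }
        next
      }
      if (sum(ok) < 3 || stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) next
      ct <- stats::cor.test(m[ok, i], m[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n), class = "correlation_matrix")
}

#' Two-sample t-test between parental lines
#'
#' Welch's test by default (`var_equal = TRUE` for the Student variant).
#' Two groups with zero variance and equal means return `t = 0, p = 1`
#' rather than an error.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param var_equal Use the pooled-variance Student test.
#' @return List with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
parental_ttest <- function(values_a, values_b, var_equal = FALSE) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(list(t = 0, p = 1, df = NA_real_,
                  mean_a = mean(values_a), mean_b = mean(values_b)))
    }
    return(list(t = Inf * sign(mean(values_a) - mean(values_b)), p = 0,
                df = NA_real_, mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Ratio between the parental trait values
#'
#' Larger over smaller, so the ratio is always `>= 1` (e.g. parental 9-week
#' tiller angles of 43.19 and 24.37 degrees give ~1.8). The summary
#' convention reports one decimal.
#'
#' @param angle_high,angle_low Positive trait values (order irrelevant).
#' @param digits Decimals in the reported ratio (default 1).
#' @return Rounded ratio.
#' @export
parental_ratio <- function(angle_high, angle_low, digits = 1) {
  if (angle_high <= 0 || angle_low <= 0) {
    stop("parental values must be positive", call. = FALSE)
  }
  round(max(angle_high, angle_low) / min(angle_high, angle_low), digits)
}

#' Stage-wise distribution summaries
#'
#' Per trait and stage: mean, s.d., five-number summary with
#' linear-interpolation quartiles (R's default type 7 convention), Tukey
#' whiskers (most extreme values within 1.5 IQR of the quartiles), and a
#' fixed-width histogram whose counts sum to the number of observations.
#'
#' @param pheno Tidy phenotype table (`line`, `stage`, `trait`, `value`).
#' @param bins Number of histogram bins.
#' @return List with `summary` (one row per trait/stage) and `histograms`
#'   (named list of `data.frame`s `mid`, `count`).
#' @export
stage_summaries <- function(pheno, bins = 10) {
  stopifnot(all(c("line", "stage", "trait", "value") %in% names(pheno)),
            nrow(pheno) > 0)
  keys <- unique(pheno[, c("trait", "stage")])
  rows <- list(); hists <- list()
  for (i in seq_len(nrow(keys))) {
    v <- pheno$value[pheno$trait == keys$trait[i] & pheno$stage == keys$stage[i]]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    iqr <- q[4] - q[2]
    wl <- min(v[v >= q[2] - 1.5 * iqr]); wh <- max(v[v <= q[4] + 1.5 * iqr])
    brk <- seq(min(v), max(v), length.out = bins + 1)
    if (min(v) == max(v)) brk <- min(v) + seq(-0.5, 0.5, length.out = bins + 1)
    cnt <- graphics::hist(v, breaks = brk, plot = FALSE)$counts
    rows[[i]] <- data.frame(trait = keys$trait[i], stage = keys$stage[i],
                            n = length(v), mean = mean(v), sd = stats::sd(v),
                            min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                            max = q[5], whisker_lo = wl, whisker_hi = wh,
                            stringsAsFactors = FALSE)
    hists[[paste(keys$trait[i], keys$stage[i], sep = "_")]] <-
      data.frame(mid = (brk[-1] + brk[-length(brk)]) / 2, count = cnt)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(summary = out, histograms = hists)
}
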