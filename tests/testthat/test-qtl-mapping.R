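# Kosambi arithmetic, genotype probabilities, the CIM scan and its
# permutation threshold, peak calling and consensus classification.

test_that("Kosambi map function matches its closed forms and inverts exactly", {
  expect_equal(kosambi_r_to_cm(0), 0)
  expect_equal(kosambi_r_to_cm(0.25), 25 * log(3), tolerance = 1e-12)
  expect_equal(round(kosambi_r_to_cm(0.25), 3), 27.465)
  ## small-r limit d -> 100 r
  expect_equal(kosambi_r_to_cm(0.001), 0.1, tolerance = 1e-5)
  r <- seq(0, 0.49, by = 0.007)
  expect_equal(kosambi_cm_to_r(kosambi_r_to_cm(r)), r, tolerance = 1e-12)
  expect_error(kosambi_r_to_cm(0.5), "0.5")
  expect_error(kosambi_cm_to_r(-1), ">= 0")
})

test_that("LOD from residual sums of squares is scaled correctly", {
  expect_equal(lod_from_rss(100, 5, 5), 0)
  expect_equal(lod_from_rss(100, 1.1, 1), 50 * log10(1.1), tolerance = 1e-12)
  expect_equal(lod_from_rss(200, 1.1, 1), 2 * lod_from_rss(100, 1.1, 1))
  expect_warning(flo <- lod_from_rss(50, 1, 2), "floored")
  expect_equal(flo, 0)
})

test_that("genotype probabilities are exact at markers and attract between", {
  map <- data.frame(marker = c("m1", "m2"), chrom = 1, pos = c(0, 20))
  g <- rbind(L1 = c("A", "A"), L2 = c("B", "B"))
  colnames(g) <- c("m1", "m2")
  pr <- genotype_probabilities(map, g, step = 1)
  at_m1 <- which(pr$positions$marker %in% "m1")
  expect_equal(pr$prob[1, at_m1], 1)
  expect_equal(pr$prob[2, at_m1], 0)
  mid <- which.min(abs(pr$positions$pos - 10))
  expect_gt(pr$prob[1, mid], 0.5)   # attraction toward flanking A/A
  expect_lt(pr$prob[2, mid], 0.5)
})

test_that("two-marker probabilities match brute-force Bayes enumeration", {
  d1 <- 7; d2 <- 13
  map <- data.frame(marker = c("m1", "m2"), chrom = 1, pos = c(0, d1 + d2))
  R1 <- ril_recombination(d1); R2 <- ril_recombination(d2)
  trans <- function(R) matrix(c(1 - R, R, R, 1 - R), 2, 2)
  configs <- expand.grid(g1 = c("A", "B", NA), g2 = c("A", "B", NA),
                         stringsAsFactors = FALSE)
  geno <- matrix(c(configs$g1, configs$g2), ncol = 2,
                 dimnames = list(paste0("L", seq_len(nrow(configs))),
                                 c("m1", "m2")))
  pr <- genotype_probabilities(map, geno, step = d1)
  mid <- which(pr$positions$pos == d1 & is.na(pr$positions$marker))
  emis <- function(code) if (is.na(code)) c(1, 1) else if (code == "A") c(1, 0) else c(0, 1)
  for (i in seq_len(nrow(configs))) {
    ## enumerate joint P(s1, sp, s2) over the 8 hidden state paths
    p_a <- 0; tot <- 0
    for (s1 in 1:2) for (sp in 1:2) for (s2 in 1:2) {
      w <- 0.5 * emis(configs$g1[i])[s1] * trans(R1)[s1, sp] *
        trans(R2)[sp, s2] * emis(configs$g2[i])[s2]
      tot <- tot + w
      if (sp == 1) p_a <- p_a + w
    }
    expect_equal(pr$prob[i, mid], p_a / tot, tolerance = 1e-10)
  }
})

test_that("the scan equals the direct-regression oracle at markers", {
  map <- mgril_map()
  cross <- simulate_cross(map, 120,
                          qtls = data.frame(chrom = 4, pos = 55, additive = 1.5),
                          stages = "5W", seed = 14)
  y <- cross$phenotypes$value
  sc <- cim_scan(map, cross$genotypes, y, step = 5)
  for (mk in c("M04_015", "M09_001", "M12_020")) {
    i <- which(sc$marker %in% mk)
    x <- ifelse(cross$genotypes[, mk] == "A", 1, -1)
    f1 <- stats::lm(y ~ x)
    lod_lm <- (length(y) / 2) *
      log10(sum(stats::resid(stats::lm(y ~ 1))^2) / sum(stats::resid(f1)^2))
    expect_equal(sc$lod[i], lod_lm, tolerance = 1e-8)
    expect_equal(sc$additive[i], unname(stats::coef(f1)[2]), tolerance = 1e-8)
    expect_equal(sc$pve[i], summary(f1)$r.squared, tolerance = 1e-8)
  }
})

test_that("cofactors enter the model outside the window: lm cross-check", {
  map <- mgril_map()
  cross <- simulate_cross(map, 100, stages = "4W", seed = 3)
  y <- cross$phenotypes$value
  cof <- c("M02_010", "M07_020")
  sc <- cim_scan(map, cross$genotypes, y, cofactors = cof, window = 10, step = 5)
  x_cof <- ifelse(cross$genotypes[, cof] == "A", 1, -1)
  ## test marker far from both cofactors: both stay in the model
  mk <- "M05_001"; i <- which(sc$marker %in% mk)
  x <- ifelse(cross$genotypes[, mk] == "A", 1, -1)
  f0 <- stats::lm(y ~ x_cof); f1 <- stats::lm(y ~ x_cof + x)
  expect_equal(sc$lod[i],
               (100 / 2) * log10(sum(stats::resid(f0)^2) / sum(stats::resid(f1)^2)),
               tolerance = 1e-8)
  ## test marker within the window of cofactor 1: that cofactor is excluded
  mk2 <- "M02_011"; j <- which(sc$marker %in% mk2)
  x2 <- ifelse(cross$genotypes[, mk2] == "A", 1, -1)
  g0 <- stats::lm(y ~ x_cof[, 2]); g1 <- stats::lm(y ~ x_cof[, 2] + x2)
  expect_equal(sc$lod[j],
               (100 / 2) * log10(sum(stats::resid(g0)^2) / sum(stats::resid(g1)^2)),
               tolerance = 1e-8)
})

test_that("LOD is invariant under affine transformation of the phenotype", {
  map <- mgril_map()
  cross <- simulate_cross(map, 80, stages = "4W", seed = 21)
  y <- cross$phenotypes$value
  s1 <- cim_scan(map, cross$genotypes, y, step = 5)
  s2 <- cim_scan(map, cross$genotypes, 3 * y + 7, step = 5)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-9)
  expect_equal(s1$pve, s2$pve, tolerance = 1e-9)
})

test_that("cofactor selection finds a strong QTL and ignores pure noise", {
  map <- mgril_map()
  hits <- 0
  for (s in 1:10) {
    cross <- simulate_cross(
      map, 162, qtls = data.frame(chrom = 6, pos = 80,
                                  additive = additive_effect_for_pve(0.4, 3)),
      stages = "5W", seed = 100 + s)
    cof <- select_cofactors(map, cross$genotypes, cross$phenotypes$value)
    pos <- map$pos[match(cof[1], map$marker)]
    if (length(cof) >= 1 && map$chrom[match(cof[1], map$marker)] == 6 &&
        abs(pos - 80) <= 10) hits <- hits + 1
  }
  expect_gte(hits, 9)
  ## null phenotype: usually no cofactors
  n_null <- vapply(1:10, function(s) {
    g <- simulate_ril_genotypes(map, 162, seed = 300 + s)
    set.seed(400 + s)
    length(select_cofactors(map, g, stats::rnorm(162)))
  }, numeric(1))
  expect_gte(mean(n_null <= 1), 0.8)
  ## max_cofactors = 0 degenerates to simple interval mapping
  g <- simulate_ril_genotypes(map, 50, seed = 1)
  set.seed(2)
  expect_identical(select_cofactors(map, g, stats::rnorm(50), max_cofactors = 0),
                   character(0))
})

test_that("permutation thresholds are deterministic and quantile-monotone", {
  map <- mgril_map()
  g <- simulate_ril_genotypes(map, 100, seed = 12)
  set.seed(5); y <- stats::rnorm(100)
  pr <- genotype_probabilities(map, g, step = 2)
  t1 <- permutation_threshold(map, g, y, n_perm = 100, seed = 9, step = 2, probs = pr)
  t2 <- permutation_threshold(map, g, y, n_perm = 100, seed = 9, step = 2, probs = pr)
  expect_identical(t1, t2)
  t3 <- permutation_threshold(map, g, y, n_perm = 100, alpha = 0.01, seed = 9,
                              step = 2, probs = pr)
  expect_gte(t3, t1)
})

test_that("conditional phenotypes are exact adjacent-stage differences", {
  pheno <- data.frame(line = rep(c("L1", "L2"), each = 3),
                      stage = rep(c("4W", "5W", "6W"), 2), trait = "TA",
                      value = c(25.1, 30.2, 31.0, 10, 10, 10))
  cond <- conditional_phenotypes(pheno, "TA")
  expect_equal(cond$value[cond$line == "L1" & cond$delta == "dT2"], 5.1)
  expect_equal(cond$value[cond$line == "L1" & cond$delta == "dT1"], 25.1)
  ## constant trajectory: all increments zero
  expect_true(all(cond$value[cond$line == "L2" & cond$delta != "dT1"] == 0))
  ## six stages yield exactly five increments
  ph6 <- data.frame(line = "L1", stage = paste0(4:9, "W"), trait = "TA",
                    value = 1:6)
  expect_equal(setdiff(unique(conditional_phenotypes(ph6, "TA")$delta), "dT1"),
               paste0("dT", 2:6))
  ## missing stage leaves the increment undefined
  ph_miss <- pheno[-2, ]
  cm <- conditional_phenotypes(ph_miss, "TA", stages = c("4W", "5W", "6W"))
  expect_true(all(is.na(cm$value[cm$line == "L1" & cm$delta %in% c("dT2", "dT3")])))
})

test_that("peak calling names, intervals and parental alleles behave", {
  map <- mgril_map()
  ## all-subthreshold scan yields no peaks
  cross0 <- simulate_cross(map, 100, stages = "4W", seed = 33)
  sc0 <- cim_scan(map, cross0$genotypes, cross0$phenotypes$value, step = 2)
  expect_equal(nrow(call_peaks(sc0, 1e6, map)), 0)

  ## one planted QTL: single peak, right chromosome, right parent
  a <- additive_effect_for_pve(0.45, 3)
  cross <- simulate_cross(map, 162,
                          qtls = data.frame(chrom = 9, pos = 70, additive = a),
                          stages = "5W", seed = 8)
  sc <- cim_scan(map, cross$genotypes, cross$phenotypes$value)
  pk <- call_peaks(sc, 3.5, map, trait = "TA", stage = "5W")
  pk9 <- pk[pk$chrom == 9, ]
  expect_equal(nrow(pk9), 1)
  expect_equal(pk9$name, "qTA9_5W")
  expect_equal(pk9$parent, "Milyang23")  # planted additive > 0
  expect_true(pk9$ci_lo <= pk9$pos && pk9$pos <= pk9$ci_hi)
  expect_true(pk9$lod >= 3.5)

  ## a Giho-increasing allele flips the parent
  crossn <- simulate_cross(map, 162,
                           qtls = data.frame(chrom = 9, pos = 70, additive = -a),
                           stages = "5W", seed = 8)
  scn <- cim_scan(map, crossn$genotypes, crossn$phenotypes$value)
  pkn <- call_peaks(scn, 3.5, map, trait = "TA", stage = "5W")
  expect_equal(pkn$parent[pkn$chrom == 9], "Giho")

  ## two QTLs 60 cM apart on one chromosome: numbered -1 suffix
  cross2 <- simulate_cross(
    map, 162, qtls = data.frame(chrom = 3, pos = c(30, 90), additive = c(a, a)),
    stages = "5W", seed = 9)
  sc2 <- cim_scan(map, cross2$genotypes, cross2$phenotypes$value)
  pk2 <- call_peaks(sc2, 3.5, map, trait = "TA", stage = "5W")
  pk23 <- pk2[pk2$chrom == 3, ]
  expect_equal(nrow(pk23), 2)
  expect_equal(pk23$name, c("qTA3_5W", "qTA3-1_5W"))
})

test_that("consensus classification follows interval overlap and direction", {
  mkpeak <- function(name, trait, chrom, lo, hi, additive) {
    data.frame(name = name, trait = trait, stage = "x", chrom = chrom,
               pos = (lo + hi) / 2, lod = 5, additive = additive, pve = 0.1,
               parent = "Milyang23", ci_lo = lo, ci_hi = hi,
               flank_lo = "f1", flank_hi = "f2", stringsAsFactors = FALSE)
  }
  cond <- rbind(mkpeak("cqTA1", "TA", 1, 10, 30, 1),
                mkpeak("cqTA5", "TA", 5, 40, 60, 1),
                mkpeak("cqTA8", "TA", 8, 0, 20, -1))
  uncond <- rbind(mkpeak("qTA1", "TA", 1, 25, 45, 1),
                  mkpeak("qTA2", "TA", 2, 40, 60, 1),
                  mkpeak("qOY8", "OY", 8, 5, 15, 1))
  out <- classify_consensus(cond, uncond, trait = "TA")
  expect_equal(out$class,
               c("conditional-consensus", "conditional-non-consensus",
                 "conditional-non-consensus"))
  expect_equal(out$overlaps[1], "qTA1")
  expect_true(out$same_direction[1])
  ## overlap with another trait's QTL is recorded but not consensus
  expect_equal(out$other_trait_overlaps[3], "qOY8")
})
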