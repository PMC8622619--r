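make_panel <- function(values, alleles, years = NULL, trait = "tw") {
  n <- length(values)
  if (is.null(years)) years <- rep(2018L, n)
  phenotype_panel(
    tibble::tibble(accession = sprintf("a%03d", seq_len(n)), year = years,
                   trait = trait, value = values),
    tibble::tibble(accession = sprintf("a%03d", seq_len(n)), marker = "mk",
                   allele = alleles)
  )
}

test_that("the one-way F statistic equals the hand-computed between/within ratio", {
  g1 <- c(9.1, 10.4, 10.0, 9.6, 10.9)   # mean ~10
  g2 <- c(12.2, 11.5, 12.8, 11.9, 11.6) # mean ~12
  p <- make_panel(c(g1, g2), rep(c("G", "T"), each = 5))
  a <- anova_per_year(p, "mk", "tw", 2018L)
  # oracle: textbook sums of squares
  gm <- mean(c(g1, g2))
  ssb <- 5 * (mean(g1) - gm)^2 + 5 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_oracle <- (ssb / 1) / (ssw / 8)
  expect_equal(a$statistic, f_oracle)
  expect_equal(a$p_value, pf(f_oracle, 1, 8, lower.tail = FALSE))
  expect_identical(a$df, c(1L, 8L))
  # group means and normal-theory CIs
  td <- tidy(a)
  expect_equal(td$mean, c(mean(g1), mean(g2)))
  expect_equal(td$conf_high[1] - td$mean[1],
               qt(.975, 4) * sd(g1) / sqrt(5))
  expect_identical(nrow(glance(a)), 1L)
})

test_that("identical group values give F = 0, p = 1; degenerate designs error", {
  v <- c(1, 2, 3, 1, 2, 3)
  p <- make_panel(v, rep(c("G", "T"), each = 3))
  a <- anova_per_year(p, "mk", "tw", 2018L)
  expect_equal(a$statistic, 0)
  expect_equal(a$p_value, 1)
  expect_error(
    anova_per_year(make_panel(1:3, c("G", "G", "T")), "mk", "tw", 2018L),
    "insufficient"
  )
  expect_error(
    anova_per_year(make_panel(1:4, rep("G", 4)), "mk", "tw", 2018L),
    "insufficient"
  )
  expect_error(anova_per_year(p, "nope", "tw", 2018L), "no genotypes")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5))
  expect_equal(fisher_exact_2x2(matrix(c(7, 7, 3, 3), 2)), 1) # independence
  set.seed(909)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 4) + c(1, 0, 0, 1), 2)
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_p(tab), tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("LS means reduce to raw means when balanced and recover planted effects when not", {
  set.seed(910)
  # balanced: 2 alleles x 3 years x 10 accessions
  n <- 30
  alleles <- rep(c("G", "T"), each = n / 2)
  phen <- tidyr::crossing(accession = sprintf("a%03d", 1:n), year = 2018:2020) |>
    dplyr::mutate(trait = "tw",
                  value = rnorm(dplyr::n(), 700) +
                    ifelse(rep(alleles, each = 3) == "T", 12, 0))
  p <- phenotype_panel(phen, tibble::tibble(accession = sprintf("a%03d", 1:n),
                                            marker = "mk", allele = alleles))
  ls <- lsmeans_two_way(p, "mk", "tw")
  raw <- phen |> dplyr::mutate(allele = rep(alleles, each = 3)) |>
    dplyr::group_by(allele) |> dplyr::summarise(m = mean(value))
  expect_equal(ls$lsmean, raw$m)
  # unbalanced with a planted year effect: LS means still recover the
  # planted genotype contrast
  keep <- !(phen$accession %in% sprintf("a%03d", 1:8) & phen$year == 2019)
  phen2 <- phen[keep, ]
  phen2$value <- phen2$value + ifelse(phen2$year == 2019, 25, 0)
  p2 <- phenotype_panel(phen2, p$genotypes)
  ls2 <- lsmeans_two_way(p2, "mk", "tw")
  expect_equal(diff(ls2$lsmean), 12, tolerance = 1)
  # invariance: relabeling years and shifting one year by a constant leaves
  # the genotype contrast untouched
  phen3 <- dplyr::mutate(phen2, year = dplyr::recode(year, `2018` = 1L,
                                                     `2019` = 2L, `2020` = 3L),
                         value = value + ifelse(year == 3L, 100, 0))
  ls3 <- lsmeans_two_way(phenotype_panel(phen3, p$genotypes), "mk", "tw")
  expect_equal(diff(ls3$lsmean), diff(ls2$lsmean), tolerance = 1e-8)
  # single year reduces to the per-year means
  one <- phenotype_panel(dplyr::filter(phen, year == 2018), p$genotypes)
  ls1 <- lsmeans_two_way(one, "mk", "tw")
  raw1 <- dplyr::filter(phen, year == 2018) |>
    dplyr::mutate(allele = alleles) |>
    dplyr::group_by(allele) |> dplyr::summarise(m = mean(value))
  expect_equal(ls1$lsmean, raw1$m)
})

test_that("allele frequencies count carriers over genotyped accessions", {
  pan <- fixture_panel()
  cfg <- fixture_cfg()
  pp <- simulate_phenotypes(pan$truth, cfg)
  af <- allele_frequency(pp, "c495")
  expect_identical(af$n[af$allele == "T"], 77L)
  expect_equal(af$pct[af$allele == "T"], 100 * 77 / 199, tolerance = 1e-10)
  expect_equal(sum(af$n), 199)
  # an accession without a genotype is reported separately as missing
  pp2 <- phenotype_panel(pp$phenotypes,
                         dplyr::filter(pp$genotypes, accession != "ACC001"))
  af2 <- allele_frequency(pp2, "c495")
  expect_identical(af2$n[is.na(af2$allele)], 1L)
  expect_true(is.na(af2$pct[is.na(af2$allele)]))
  expect_equal(sum(af2$pct, na.rm = TRUE), 100)
  # all-same panel -> 100%
  same <- make_panel(1:4, rep("G", 4))
  expect_equal(allele_frequency(same, "mk")$pct, 100)
})

test_that("score-trait Fisher test builds the carrier x dichotomized-score table", {
  pan <- fixture_panel()
  pp <- simulate_phenotypes(pan$truth, fixture_cfg())
  st <- score_trait_fisher(pp, "c495", "lodging", 2018L, "T")
  expect_identical(dim(st$table), c(2L, 2L))
  expect_identical(sum(st$table), 199L)
  expect_identical(st$p_value, fisher_exact_2x2(st$table))
  # the planted carrier shift on lodging is detectable
  expect_lt(st$p_value, 0.05)
})

test_that("under the null the per-year F-test p-values are uniform", {
  truth <- simulate_panel(fixture_model(),
                          sim_config(seed = 21L, n_accessions = 60L))$truth
  pvals <- vapply(1:300, function(i) {
    cfg0 <- sim_config(seed = 40000L + i, n_accessions = 60L,
                       effect_sizes = c(heading_date = 0),
                       noise_sd = c(heading_date = 2),
                       trait_baselines = c(heading_date = 200))
    pp <- simulate_phenotypes(truth, cfg0)
    anova_per_year(pp, "c495", "heading_date", 2018L)$p_value
  }, 1)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the assoc scan flattens per-year results and adjusts optionally", {
  pan <- fixture_panel()
  pp <- simulate_phenotypes(pan$truth, fixture_cfg())
  sc <- assoc_scan(pp, "c495", traits = c("heading_date", "test_weight"))
  expect_s3_class(sc, "grf_assoc_scan")
  expect_identical(nrow(sc), 2L * 3L * 2L)  # traits x years x alleles
  expect_true(all(c("mean", "conf_low", "conf_high", "p_value") %in% names(sc)))
  sc2 <- assoc_scan(pp, "c495", traits = "heading_date", p_adjust = TRUE)
  expect_true("p_adj" %in% names(sc2))
  expect_true(all(sc2$p_adj >= sc2$p_value))
  pl <- ggplot2::autoplot(sc)
  expect_s3_class(pl, "ggplot")
})
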