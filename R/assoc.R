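# Marker-trait association statistics: per-year one-way F-tests, three-year
# least-squares means from the additive genotype + year model, Fisher's
# exact test for score traits, and allele-frequency tabulation.

#' Bundle phenotype and genotype tables into a panel
#'
#' @param phenotypes Tibble with columns `accession`, `year`, `trait`,
#'   `value` (one value per accession x year x trait).
#' @param genotypes Tibble with columns `accession`, `marker`, `allele`
#'   (allele class per marker; accessions absent for a marker are treated
#'   as missing).
#' @return An object of class `grf_phenotype_panel`.
#' @export
phenotype_panel <- function(phenotypes, genotypes) {
  need <- c("accession", "year", "trait", "value")
  if (!all(need %in% names(phenotypes))) {
    abort("`phenotypes` needs columns accession, year, trait, value")
  }
  if (!all(c("accession", "marker", "allele") %in% names(genotypes))) {
    abort("`genotypes` needs columns accession, marker, allele")
  }
  dup <- phenotypes |>
    dplyr::count(.data$accession, .data$year, .data$trait) |>
    filter(.data$n > 1L)
  if (nrow(dup)) abort("more than one value per accession x year x trait")
  structure(list(phenotypes = as_tibble(phenotypes),
                 genotypes = as_tibble(genotypes)),
            class = "grf_phenotype_panel")
}

#' @export
print.grf_phenotype_panel <- function(x, ...) {
  cat(sprintf(
    "<grf_phenotype_panel> %d accessions, %d years, traits: %s; markers: %s\n",
    length(unique(x$phenotypes$accession)),
    length(unique(x$phenotypes$year)),
    paste(unique(x$phenotypes$trait), collapse = ", "),
    paste(unique(x$genotypes$marker), collapse = ", ")
  ))
  invisible(x)
}

# joined analysis data for one marker/trait (+ optional year); listwise drop
.assoc_data <- function(panel, marker, trait, year = NULL) {
  stopifnot(inherits(panel, "grf_phenotype_panel"))
  g <- filter(panel$genotypes, .data$marker == !!marker)
  if (nrow(g) == 0L) abort(sprintf("no genotypes for marker '%s'", marker))
  d <- panel$phenotypes |>
    filter(.data$trait == !!trait) |>
    left_join(select(g, "accession", "allele"), by = "accession") |>
    filter(!is.na(.data$value), !is.na(.data$allele))
  if (!is.null(year)) d <- filter(d, .data$year == !!year)
  if (nrow(d) == 0L) abort("insufficient data: no observations after filtering")
  d
}

#' Per-year one-way F-test of a marker-trait association
#'
#' One-way analysis of variance of the trait values of one year across the
#' marker's allele classes (the between-genotype F-test), with per-group
#' means and normal-theory 95% confidence intervals.
#'
#' @param panel A [phenotype_panel()].
#' @param marker Marker name in the genotype table.
#' @param trait Trait name.
#' @param year Year to analyze.
#' @return A `grf_assoc` object; see [tidy()] / [glance()] methods.
#' @export
anova_per_year <- function(panel, marker, trait, year) {
  d <- .assoc_data(panel, marker, trait, year)
  sizes <- table(d$allele)
  if (length(sizes) < 2L || sum(sizes >= 2L) < 2L) {
    abort("insufficient data: need >= 2 genotype groups with >= 2 members each")
  }
  fit <- aov(value ~ allele, data = mutate(d, allele = factor(.data$allele)))
  an <- anova(fit)
  groups <- d |>
    group_by(allele = .data$allele) |>
    summarise(
      n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
      .groups = "drop"
    ) |>
    mutate(
      se = .data$sd / sqrt(.data$n),
      conf_low = .data$mean - qt(0.975, .data$n - 1L) * .data$se,
      conf_high = .data$mean + qt(0.975, .data$n - 1L) * .data$se
    )
  structure(
    list(marker = marker, trait = trait, year = year, groups = groups,
         statistic = an$`F value`[1L], df = c(an$Df[1L], an$Df[2L]),
         p_value = an$`Pr(>F)`[1L], n = nrow(d)),
    class = "grf_assoc"
  )
}

#' @export
print.grf_assoc <- function(x, ...) {
  cat(sprintf("<grf_assoc> %s ~ %s, year %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$trait, x$marker, x$year, x$df[1L], x$df[2L],
              x$statistic, x$p_value))
  print(x$groups)
  invisible(x)
}

#' Tidy a per-year association result
#'
#' @param x A `grf_assoc` object.
#' @param ... Unused.
#' @return `tidy()`: one row per allele group with mean and 95% CI;
#'   `glance()`: a one-row model summary (F statistic, df, p).
#' @method tidy grf_assoc
#' @export
tidy.grf_assoc <- function(x, ...) {
  mutate(x$groups, trait = x$trait, year = x$year, marker = x$marker,
         .before = 1L)
}

#' @rdname tidy.grf_assoc
#' @method glance grf_assoc
#' @export
glance.grf_assoc <- function(x, ...) {
  tibble(trait = x$trait, year = x$year, marker = x$marker,
         statistic = x$statistic, df1 = x$df[1L], df2 = x$df[2L],
         p_value = x$p_value, n = x$n)
}

#' Scan all trait x year combinations for one marker
#'
#' Runs [anova_per_year()] for every combination of the requested traits
#' and years, returning a flat tibble ready for plotting (see
#' [autoplot.grf_assoc_scan()]). Raw p-values are reported, matching the
#' per-trait presentation of field-trial studies; set `p_adjust = TRUE` for
#' an additional Benjamini-Hochberg column.
#'
#' @inheritParams anova_per_year
#' @param traits,years Subsets to scan (default: all present).
#' @param p_adjust Add a `p_adj` (Benjamini-Hochberg across the scan)
#'   column. Off by default.
#' @return A tibble of class `grf_assoc_scan`: one row per trait, year and
#'   allele group, with `mean`, `conf_low`, `conf_high`, `statistic`,
#'   `p_value`.
#' @export
assoc_scan <- function(panel, marker, traits = NULL, years = NULL,
                       p_adjust = FALSE) {
  stopifnot(inherits(panel, "grf_phenotype_panel"))
  traits <- traits %||% unique(panel$phenotypes$trait)
  years <- years %||% sort(unique(panel$phenotypes$year))
  rows <- purrr::map_dfr(traits, function(tr) {
    purrr::map_dfr(years, function(yr) {
      a <- anova_per_year(panel, marker, tr, yr)
      mutate(tidy(a), statistic = a$statistic, p_value = a$p_value)
    })
  })
  if (p_adjust) {
    key <- rows |> dplyr::distinct(.data$trait, .data$year, .data$p_value) |>
      mutate(p_adj = stats::p.adjust(.data$p_value, "BH"))
    rows <- left_join(rows, key, by = c("trait", "year", "p_value"))
  }
  structure(rows, class = c("grf_assoc_scan", class(rows)))
}

#' Least-squares genotype means over years
#'
#' Fits the additive two-way model `value ~ allele + year` (year as a
#' factor) by least squares and reports the genotype LS means averaged over
#' the year levels with equal weight. With balanced data these reduce to
#' the arithmetic group means; with a single year they equal the per-year
#' means. Genotype levels that are inestimable under a rank-deficient
#' design are flagged (`estimable = FALSE`, `lsmean = NA`).
#'
#' @inheritParams anova_per_year
#' @return Tibble: `allele`, `lsmean`, `se`, `df`, `conf_low`, `conf_high`,
#'   `estimable`.
#' @export
lsmeans_two_way <- function(panel, marker, trait) {
  d <- .assoc_data(panel, marker, trait)
  d <- mutate(d, allele = factor(.data$allele), year = factor(.data$year))
  fit <- if (length(levels(d$year)) > 1L) {
    lm(value ~ allele + year, data = d)
  } else {
    lm(value ~ allele, data = d)
  }
  emm <- summary(emmeans::emmeans(fit, "allele"))
  tibble(
    allele = as.character(emm$allele),
    lsmean = emm$emmean, se = emm$SE, df = emm$df,
    conf_low = emm$lower.CL, conf_high = emm$upper.CL,
    estimable = !is.na(emm$emmean)
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value: the sum of probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's.
#'
#' @param table A 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return The two-sided p-value (numeric scalar).
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)) # 2/choose(10, 5)
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) abort("`table` must be 2x2")
  if (any(is.na(table)) || any(table < 0) || any(table != round(table))) {
    abort("`table` must hold non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("empty margin: every row and column total must be positive")
  }
  fisher.test(table, conf.int = FALSE)$p.value
}

#' Fisher's exact test for a score trait
#'
#' Builds the 2x2 table of carrier status (marker allele equal to
#' `carrier_allele`) against the score dichotomized at its median (above vs
#' not above) and applies [fisher_exact_2x2()].
#'
#' @inheritParams anova_per_year
#' @param carrier_allele The allele class defining carriers.
#' @return List: `table` (the 2x2 counts) and `p_value`.
#' @export
score_trait_fisher <- function(panel, marker, trait, year, carrier_allele) {
  d <- .assoc_data(panel, marker, trait, year)
  carrier <- factor(d$allele == carrier_allele, levels = c(TRUE, FALSE),
                    labels = c("carrier", "non-carrier"))
  high <- factor(d$value > median(d$value), levels = c(TRUE, FALSE),
                 labels = c("above", "at_or_below"))
  tab <- table(carrier, high)
  list(table = unclass(tab), p_value = fisher_exact_2x2(tab))
}

#' Allele carrier counts and percentages for a marker
#'
#' Percentages are computed over genotyped (non-missing) accessions;
#' accessions without a genotype for the marker are reported separately as
#' a `NA`-allele row with `pct = NA`.
#'
#' @inheritParams anova_per_year
#' @return Tibble: `allele`, `n`, `pct`.
#' @export
allele_frequency <- function(panel, marker) {
  stopifnot(inherits(panel, "grf_phenotype_panel"))
  acc <- unique(panel$phenotypes$accession)
  g <- panel$genotypes |>
    filter(.data$marker == !!marker) |>
    select("accession", "allele")
  d <- tibble(accession = acc) |> left_join(g, by = "accession")
  typed <- filter(d, !is.na(.data$allele))
  out <- typed |>
    dplyr::count(.data$allele, name = "n") |>
    mutate(pct = 100 * .data$n / nrow(typed)) |>
    arrange(desc(.data$n))
  n_missing <- sum(is.na(d$allele))
  if (n_missing > 0L) {
    out <- bind_rows(out, tibble(allele = NA_character_, n = n_missing,
                                 pct = NA_real_))
  }
  out
}
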