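# Seeded synthetic-data generator.
#
# The generator builds a surrogate gene region honoring every coordinate
# constraint printed for the real locus: a 4-exon gene on chr2A (plus
# strand) whose CDS position 495 sits at g.687050412, a 1035-nt CDS
# (345 codons) with a polyglutamine tract at residues 38..44, an (AG)n
# microsatellite in the 5'UTR, the published marker primer sites planted so
# that the diagnostic PCR/CAPS/SSR product sizes are reproduced exactly,
# and reference bases fixed at every catalog variant position. Intron
# lengths are 320/410/500 nt and the 5'/3' UTRs 490/330 nt; these are the
# package's own surrogate choices (the real intron/UTR lengths are not
# reproduced), chosen once so all printed genomic coordinates fall inside
# the slice at the printed flank lengths.

.G <- local({
  cds_g <- 687049188L               # genomic position of the A of ATG
  intron_len <- c(320L, 410L, 500L) # after CDS bases 100, 325, 689
  cds_break <- c(100L, 325L, 689L)
  cds_len <- 1035L
  utr5_len <- 490L
  utr3_len <- 330L
  exon1_start <- cds_g - utr5_len                    # 687048698 (TSS)
  exon1_end <- cds_g + 99L                           # 687049287
  exon2_start <- exon1_end + intron_len[1] + 1L      # 687049608
  exon2_end <- exon2_start + (325L - 101L)           # 687049832
  exon3_start <- exon2_end + intron_len[2] + 1L      # 687050243
  exon3_end <- exon3_start + (689L - 326L)           # 687050606
  exon4_start <- exon3_end + intron_len[3] + 1L      # 687051107
  cds_end <- exon4_start + (cds_len - 690L)          # 687051452
  exon4_end <- cds_end + utr3_len                    # 687051782
  list(
    contig = "chr2A", cds_g = cds_g, cds_len = cds_len,
    utr5_len = utr5_len, utr3_len = utr3_len,
    exons = cbind(c(exon1_start, exon2_start, exon3_start, exon4_start),
                  c(exon1_end, exon2_end, exon3_end, exon4_end)),
    cds_end = cds_end,
    introns = cbind(c(exon1_end, exon2_end, exon3_end) + 1L,
                    c(exon2_start, exon3_start, exon4_start) - 1L),
    promoter_end = exon1_start - 1L,
    # SSR block in the 5'UTR: F primer, spacer, guard, (AG)26 tract, guard
    ssr_f_start = 687048740L, ssr_tract_start = 687048844L, ssr_ref_repeats = 26L,
    ssr_rrc_start = 687048980L, ssr_window = c(687048840L, 687048925L),
    # fixed reference bases at catalog variant positions
    fixed_bases = c(
      "687048137" = "G", "687048328" = "A", "687048382" = "C", "687048627" = "G",
      "687049048" = "A",                                      # c.-140
      "687052487" = "C", "687052488" = "T", "687052489" = "A" # 3' flank
    ),
    utr5_del_start = 687049086L,                              # c.-102_-91
    utr5_del_seq = "ACGTACGTACGT", utr5_del_guard = "C",
    intron2_fix_start = 687049862L, intron2_fix = "GACAGA",   # hosts +32_+33insTCC
    intron2_bases = c("687050001" = "G",                      # c.325+169
                      "687050069" = "A",                      # c.326-174
                      "687050204" = "A"),                     # c.326-39
    intron3_bases = c("687050742" = "A",                      # c.689+136
                      "687050847" = "T"),                     # c.689+241
    utr3_bases = c("687051460" = "C",                         # c.*8
                   "687051737" = "A",                         # c.*285
                   "687051764" = "A"),                        # c.*312
    # published marker primers, planted so products are 344 / 454 / 208+2n bp
    q42_f = "CTTCTATCTGTAGCTCGAGGTGT",   q42_f_start = 687049483L,
    q42_r = "GTGGTAGGAGGAGGAGGAATCTA",   q42_rrc_start = 687049804L,
    q165_f = "GGGTTTTCTTAATTTGCTTGCAGT", q165_f_start = 687050218L,
    q165_r = "CAGAAGATAAAAACGGCAGGTGA",  q165_rrc_start = 687050649L,
    ssr_f = "TCTCACCAGGCAGCAGATCG",
    ssr_r = "ACAGGGAGGCAAAGGGCATC",
    q165_amplicon = c(687050218L, 687050671L)
  )
})

.CODONS61 <- {
  b <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Default allele catalog for the synthetic panel
#'
#' One row per named allele: the variant set (full-form HGVS names, all
#' 3'-normalized on the synthetic reference), the microsatellite repeat
#' count (`ssr_n` units of AG; `ssr_interrupted` alleles lose one A, giving
#' a tract of `2 * ssr_n - 1` nt), the encoded protein isoform letter and
#' the population frequency. Defaults replay the printed variant catalog:
#' the frequent promoter SNP, the 5'UTR deletion + SNP of the wild-emmer
#' haplotype, the T.-urartu-like intron/UTR/coding set, the c.495G>T allele
#' at carrier frequency 0.39, and the rare 9-nt polyglutamine deletion.
#'
#' @return A tibble with columns `allele`, `variants` (list of character),
#'   `ssr_n`, `ssr_interrupted`, `isoform`, `freq`.
#' @export
grf_allele_catalog <- function() {
  prom <- "g.687048627G>C"
  urartu <- c(
    "c.528G>C", "c.530C>G", "c.729C>G",
    "c.325+32_325+33insTCC", "c.325+169G>C", "c.326-39A>G", "c.326-174A>G",
    "c.689+136A>G", "c.689+241T>C",
    "c.*285A>G", "c.*312A>T", "g.687052487C>T",
    prom, "g.687048328A>G"
  )
  emmer <- c(prom, "g.687048328A>G", "c.-140A>G", "c.-102_-91del",
             "g.687052487_687052488del")
  tibble(
    allele = c("a1", "a2", "a3", "a4", "a6", "a10", "a16", "a17",
               "b1", "b2", "c1", "d1"),
    variants = list(
      character(0), prom, prom,
      c(prom, "g.687048382C>T"), c(prom, "g.687048137G>T"),
      c(prom, "c.*8C>T"), emmer, prom,
      c("c.495G>T", prom), c("c.495G>T", prom),
      urartu, "c.126_134del"
    ),
    ssr_n = c(26L, 28L, 31L, 24L, 22L, 20L, 18L, 37L, 30L, 32L, 11L, 26L),
    ssr_interrupted = c(FALSE, TRUE, TRUE, rep(FALSE, 9L)),
    isoform = c(rep("A", 8L), "B", "B", "C", "D"),
    freq = c(0.30, 0.09, 0.04, 0.05, 0.04, 0.03, 0.01, 0.02,
             0.30, 0.09, 0.02, 0.01)
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults are
#' the study conditions: flanks of 1075 / 1389 nt around the CDS, a 4-exon
#' gene, an (AG)n microsatellite with panel repeat counts in 11..37, a
#' 7-residue polyglutamine tract starting at residue 38, a 199-accession
#' panel with the [grf_allele_catalog()] frequencies, three trial years and
#' planted carrier effects on the b allele.
#'
#' @param seed Integer seed; fixes every downstream draw.
#' @param n_accessions Panel size.
#' @param flank5,flank3 Stored flank lengths (nt) before the start codon /
#'   after the stop codon.
#' @param exon_count Number of exons; the catalog-hosting reference
#'   requires 4.
#' @param ssr_repeat_range Inclusive range of panel microsatellite repeat
#'   counts.
#' @param polyq_length Number of consecutive glutamine residues from
#'   residue 38.
#' @param allele_catalog Allele catalog tibble (see [grf_allele_catalog()]).
#' @param random_snps Extra random non-coding SNVs per accession (default 0
#'   keeps the panel an exact catalog replay).
#' @param effect_allele Isoform letter (lowercase) whose carriers receive
#'   `effect_sizes`.
#' @param effect_sizes,noise_sd,trait_baselines Named per-trait vectors
#'   (days after sowing for `heading_date`, g/L `test_weight`, g per 1000
#'   kernels `kernel_weight`, % `protein`, t/ha `yield`).
#' @param year_effects Trait-by-year matrix of additive year shifts.
#' @param years Trial years.
#' @param score_p0,score_shift Baseline probability and carrier shift of the
#'   binomial score trait (`lodging`, scored 1..9).
#' @return An object of class `grf_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_accessions = 199L,
                       flank5 = 1075L, flank3 = 1389L,
                       exon_count = 4L,
                       ssr_repeat_range = c(11L, 37L),
                       polyq_length = 7L,
                       allele_catalog = grf_allele_catalog(),
                       random_snps = 0L,
                       effect_allele = "b",
                       effect_sizes = c(heading_date = -2, test_weight = 10,
                                        kernel_weight = 2, protein = 0.3,
                                        yield = -0.2),
                       noise_sd = c(heading_date = 2, test_weight = 15,
                                    kernel_weight = 3, protein = 0.8,
                                    yield = 0.8),
                       trait_baselines = c(heading_date = 200, test_weight = 780,
                                           kernel_weight = 40, protein = 14,
                                           yield = 7),
                       year_effects = NULL,
                       years = c(2018L, 2019L, 2020L),
                       score_p0 = 0.45, score_shift = -0.15) {
  stopifnot(.is_count(seed), .is_count(n_accessions), n_accessions >= 1,
            .is_count(flank5), .is_count(flank3), .is_count(polyq_length),
            length(ssr_repeat_range) == 2L,
            ssr_repeat_range[1] >= 2L, ssr_repeat_range[2] >= ssr_repeat_range[1])
  traits <- names(trait_baselines)
  if (is.null(year_effects)) {
    year_effects <- rbind(
      heading_date  = c(0, 2, -3), test_weight = c(0, -12, 8),
      kernel_weight = c(0, 3, -2), protein = c(0, -0.5, 0.4),
      yield         = c(0, 0.6, -0.9)
    )[traits, seq_along(years), drop = FALSE]
  }
  colnames(year_effects) <- as.character(years)
  if (abs(sum(allele_catalog$freq) - 1) > 1e-8) {
    abort("allele catalog frequencies must sum to 1")
  }
  structure(
    list(seed = as.integer(seed), n_accessions = as.integer(n_accessions),
         flank5 = as.integer(flank5), flank3 = as.integer(flank3),
         exon_count = as.integer(exon_count),
         ssr_repeat_range = as.integer(ssr_repeat_range),
         polyq_length = as.integer(polyq_length),
         allele_catalog = allele_catalog, random_snps = as.integer(random_snps),
         effect_allele = effect_allele, effect_sizes = effect_sizes,
         noise_sd = noise_sd, trait_baselines = trait_baselines,
         year_effects = year_effects, years = as.integer(years),
         score_p0 = score_p0, score_shift = score_shift),
    class = "grf_sim_config"
  )
}

#' Generate the synthetic reference gene model
#'
#' Builds the surrogate reference described in the package vignette: fixed
#' gene geometry, seeded random background, the polyglutamine tract, the
#' 5'UTR (AG)26 microsatellite, planted marker primer sites and fixed bases
#' at every catalog variant position. The same seed always yields the same
#' sequence byte-for-byte.
#'
#' @param cfg A [sim_config()].
#' @return A [gene_model()] with `ssr_locus` set.
#' @export
simulate_reference <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "grf_sim_config"))
  G <- .G
  if (cfg$exon_count != 4L) {
    abort("the catalog-hosting reference requires exon_count = 4 (use random_gene_model() for other structures)")
  }
  if (cfg$flank5 < 700L || cfg$flank3 < 1045L) {
    abort("flanks too short to host the variant catalog coordinates (need flank5 >= 700, flank3 >= 1045)")
  }
  if (cfg$polyq_length < 7L || 38L + cfg$polyq_length >= 164L) {
    abort("polyq_length must be >= 7 (the 9-nt deletion spans residues 42..44) and < 126")
  }
  offset <- G$cds_g - cfg$flank5
  g_end <- G$cds_end + cfg$flank3
  L <- g_end - offset + 1L
  idx <- function(g) g - offset + 1L

  sv <- .with_seed(cfg$seed, {
    sv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

    # CDS: random non-stop codons, then fixed codons
    n_codons <- G$cds_len / 3L
    codons <- sample(.CODONS61, n_codons, replace = TRUE)
    codons[1L] <- "ATG"
    codons[37L] <- "GCT"
    codons[38L:(37L + cfg$polyq_length)] <- "CAG"
    codons[38L + cfg$polyq_length] <- "CAT"
    codons[164L] <- "CAG"; codons[165L] <- "CAG"; codons[166L] <- "CTG"
    codons[176L] <- "CAG"; codons[177L] <- "GCT"
    codons[243L] <- "GAC"
    codons[n_codons] <- "TGA"
    cds <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1]]

    seg <- rbind(
      c(G$cds_g, G$cds_g + 99L),            # c.1..100
      c(G$exons[2L, 1L], G$exons[2L, 2L]),  # c.101..325
      c(G$exons[3L, 1L], G$exons[3L, 2L]),  # c.326..689
      c(G$exons[4L, 1L], G$cds_end)         # c.690..1035
    )
    cpos <- 1L
    for (k in seq_len(nrow(seg))) {
      w <- seg[k, 2L] - seg[k, 1L] + 1L
      sv[idx(seg[k, 1L]):idx(seg[k, 2L])] <- cds[cpos:(cpos + w - 1L)]
      cpos <- cpos + w
    }

    # splice motifs (cosmetic; splicing uses the annotated exon intervals)
    for (k in seq_len(nrow(G$introns))) {
      sv[idx(G$introns[k, 1L]) + 0:1] <- c("G", "T")
      sv[idx(G$introns[k, 2L]) - 1:0] <- c("A", "G")
    }

    put <- function(gstart, s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      sv[idx(gstart) + seq_along(ch) - 1L] <<- ch
    }

    # 5'UTR microsatellite block
    put(G$ssr_f_start, G$ssr_f)
    tract <- strrep("AG", G$ssr_ref_repeats)
    scrub <- function(g1, g2) {  # pyrimidine-only margins: no stray AG runs
      n <- idx(g2) - idx(g1) + 1L
      sv[idx(g1):idx(g2)] <<- sample(c("C", "T"), n, replace = TRUE)
    }
    scrub(G$ssr_window[1L] - 4L, G$ssr_tract_start - 1L)
    put(G$ssr_tract_start, tract)
    scrub(G$ssr_tract_start + nchar(tract), G$ssr_window[2L] + 5L)
    put(G$ssr_rrc_start, revcomp(G$ssr_r))

    # fixed bases at catalog variant positions (skip any outside the slice)
    put_fixed <- function(bases) {
      for (g in names(bases)) {
        gi <- as.integer(g)
        if (gi >= offset && gi <= g_end) sv[idx(gi)] <<- bases[[g]]
      }
    }
    put_fixed(G$fixed_bases)
    put(G$utr5_del_start, paste0(G$utr5_del_seq, G$utr5_del_guard))
    put(G$intron2_fix_start, G$intron2_fix)
    put_fixed(G$intron2_bases)
    put_fixed(G$intron3_bases)
    put_fixed(G$utr3_bases)

    # diagnostic marker primer sites
    put(G$q42_f_start, G$q42_f)
    put(G$q42_rrc_start, revcomp(G$q42_r))
    put(G$q165_f_start, G$q165_f)
    put(G$q165_rrc_start, revcomp(G$q165_r))

    # remove stray SfaN I recognition sites (either strand) from the CAPS
    # amplicon so the G allele digests to a single intact fragment
    amp <- idx(G$q165_amplicon)
    locked <- c(
      idx(G$q165_f_start) + 0:(nchar(G$q165_f) - 1L),
      idx(G$q165_rrc_start) + 0:(nchar(G$q165_r) - 1L),
      idx(G$cds_g + 489L + 0:8)  # codons 164..166 engineer the c.495 site
    )
    cds_codon_at <- function(i) {
      g <- offset + i - 1L
      if (g < G$exons[3L, 1L] || g > G$exons[3L, 2L]) return(NULL)
      cp <- 326L + (g - G$exons[3L, 1L])
      cdn <- (cp - 1L) %/% 3L
      first_g <- G$exons[3L, 1L] + (cdn * 3L + 1L - 326L)
      list(pos_in_codon = cp - (cdn * 3L), first_i = idx(first_g))
    }
    for (pass in 1:20) {
      s_now <- paste(sv[amp[1L]:amp[2L]], collapse = "")
      hits <- c(.find_all(s_now, "GCATC"), .find_all(s_now, "GATGC"))
      if (length(hits) == 0L) break
      if (pass == 20L) abort("could not clean stray restriction sites")
      for (h in hits) {
        cand <- (amp[1L] + h - 1L) + 2L  # middle base of the 5-mer
        if (cand %in% locked) cand <- (amp[1L] + h - 1L) + 1L
        if (cand %in% locked) next
        cc <- cds_codon_at(cand)
        for (b in setdiff(c("A", "C", "G", "T"), sv[cand])) {
          old <- sv[cand]; sv[cand] <- b
          ok <- TRUE
          if (!is.null(cc)) {
            codon <- paste(sv[cc$first_i + 0:2], collapse = "")
            ok <- !codon %in% c("TAA", "TAG", "TGA")
          }
          if (ok) break
          sv[cand] <- old
        }
      }
    }
    sv
  })

  seq <- paste(sv, collapse = "")
  for (p in c(G$q42_f, revcomp(G$q42_r), G$q165_f, revcomp(G$q165_r))) {
    if (length(.find_all(seq, p)) + length(.find_all(seq, revcomp(p))) != 1L) {
      abort("primer site not unique in the synthetic reference")  # ~4^-23 event
    }
  }

  gene_model(
    contig = G$contig, offset = offset, sequence = seq, strand = "+",
    exons = G$exons, cds_start = G$cds_g, cds_end = G$cds_end,
    promoter_window = c(offset, G$promoter_end),
    ssr_locus = list(unit = "AG", window = G$ssr_window)
  )
}

# largest-remainder allocation of panel counts to catalog alleles
.allocate_counts <- function(freq, n) {
  raw <- freq * n
  counts <- floor(raw)
  rem <- raw - counts
  short <- n - sum(counts)
  if (short > 0L) {
    give <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[give] <- counts[give] + 1L
  }
  as.integer(counts)
}

# build an allele's SSR tract replacement as a plain variant row
.ssr_replacement <- function(model, n, interrupted) {
  G <- .G
  ref_tract <- strrep("AG", G$ssr_ref_repeats)
  tract <- if (interrupted) {
    k <- n %/% 2L  # drop the A of the (k+1)-th unit
    paste0(strrep("AG", k), "G", strrep("AG", n - k - 1L))
  } else {
    strrep("AG", n)
  }
  if (identical(tract, ref_tract)) return(NULL)
  tibble(gstart = G$ssr_tract_start,
         gend = G$ssr_tract_start + nchar(ref_tract) - 1L,
         ref = ref_tract, alt = tract)
}

#' Generate the per-accession haplotype panel
#'
#' Applies each catalog allele's variant set and microsatellite tract to the
#' reference and assigns accessions to alleles. Counts follow the catalog
#' frequencies by largest-remainder allocation (not multinomial sampling),
#' so counts are deterministic and every allele whose expected count reaches
#' one is always present; the accession -> allele assignment order is
#' shuffled under the seed. Each catalog name is
#' checked to be the 3'-normalized HGVS form on this reference.
#'
#' @param model The reference from [simulate_reference()].
#' @param cfg The same [sim_config()].
#' @return List with `sequences` (named character vector), `truth` (tibble:
#'   `accession`, `allele`, `isoform`, `variants` list-column,
#'   `ssr_repeat_count`, `ssr_tract_length`, `ssr_interrupted`) and
#'   `allele_effects` (tibble of planted per-trait effects per allele).
#' @export
simulate_panel <- function(model, cfg = sim_config()) {
  stopifnot(inherits(model, "grf_gene_model"), inherits(cfg, "grf_sim_config"))
  cat <- cfg$allele_catalog
  if (any(cat$ssr_n < cfg$ssr_repeat_range[1L] | cat$ssr_n > cfg$ssr_repeat_range[2L])) {
    abort("catalog ssr_n outside ssr_repeat_range")
  }

  allele_seq <- character(nrow(cat))
  parsed <- vector("list", nrow(cat))
  for (i in seq_len(nrow(cat))) {
    rows <- purrr::map_dfr(cat$variants[[i]], function(nm) {
      row <- parse_hgvs(model, nm)
      want <- sub("^[A-Za-z0-9_.]+:", "", nm)
      got <- if (startsWith(want, "c.")) row$name_c else sub("^[A-Za-z0-9_.]+:", "", row$name_g)
      if (!identical(got, want)) {
        abort(sprintf("catalog variant '%s' is not 3'-normalized on this reference (canonical: %s)",
                      nm, got))
      }
      row
    })
    ssr_row <- .ssr_replacement(model, cat$ssr_n[i], cat$ssr_interrupted[i])
    all_rows <- bind_rows(
      if (nrow(rows)) rows[, c("gstart", "gend", "ref", "alt")],
      ssr_row
    )
    parsed[[i]] <- rows
    allele_seq[i] <- if (is.null(all_rows) || nrow(all_rows) == 0L) {
      model$sequence
    } else {
      apply_variants(model, all_rows)
    }
  }

  counts <- .allocate_counts(cat$freq, cfg$n_accessions)
  acc <- sprintf("ACC%03d", seq_len(cfg$n_accessions))
  assign_idx <- rep(seq_len(nrow(cat)), counts)
  assign_idx <- .with_seed(cfg$seed + 1L, sample(assign_idx))

  sequences <- setNames(allele_seq[assign_idx], acc)

  if (cfg$random_snps > 0L) {
    sequences <- .with_seed(cfg$seed + 7L, {
      # extra random non-coding SNVs outside exons and the SSR window
      offs <- model$offset
      gall <- offs:(offs + nchar(model$sequence) - 1L)
      exonic <- rep(FALSE, length(gall))
      for (k in seq_len(nrow(model$exons))) {
        exonic[(model$exons[k, 1L]:model$exons[k, 2L]) - offs + 1L] <- TRUE
      }
      ssr <- model$ssr_locus$window
      ok <- !exonic
      ok[(max(ssr[1L] - 10L, offs):(ssr[2L] + 10L)) - offs + 1L] <- FALSE
      pool <- gall[ok]
      vapply(sequences, function(s) {
        pos <- sample(pool, cfg$random_snps)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        for (g in pos) {
          i <- g - offs + 1L
          ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
        }
        paste(ch, collapse = "")
      }, "")
    })
  }

  tract_len <- ifelse(cat$ssr_interrupted, 2L * cat$ssr_n - 1L, 2L * cat$ssr_n)
  truth <- tibble(
    accession = acc,
    allele = cat$allele[assign_idx],
    isoform = cat$isoform[assign_idx],
    variants = cat$variants[assign_idx],
    ssr_repeat_count = ifelse(cat$ssr_interrupted, cat$ssr_n - 1L, cat$ssr_n)[assign_idx],
    ssr_tract_length = tract_len[assign_idx],
    ssr_interrupted = cat$ssr_interrupted[assign_idx]
  )

  carrier <- tolower(cat$isoform) == cfg$effect_allele
  allele_effects <- tidyr::crossing(
    allele = cat$allele,
    trait = names(cfg$effect_sizes)
  ) |>
    left_join(tibble(allele = cat$allele, carrier = carrier), by = "allele") |>
    mutate(effect = ifelse(.data$carrier, cfg$effect_sizes[.data$trait], 0)) |>
    select("allele", "trait", "effect")

  list(sequences = sequences, truth = truth, allele_effects = allele_effects)
}

#' Generate phenotype and genotype panels with planted effects
#'
#' Continuous traits follow `baseline + year effect + allele effect (for
#' carriers of the effect allele) + N(0, noise_sd)` for each year; the
#' score trait `lodging` is `1 + Binomial(8, p)` with a carrier-shifted
#' probability. The genotype table records the diagnostic `c495` marker
#' (allele T for carriers of the b allele, G otherwise).
#'
#' @param truth The `truth` tibble from [simulate_panel()].
#' @param cfg The same [sim_config()].
#' @return A [phenotype_panel()].
#' @export
simulate_phenotypes <- function(truth, cfg = sim_config()) {
  stopifnot(is.data.frame(truth), inherits(cfg, "grf_sim_config"))
  carrier <- tolower(truth$isoform) == cfg$effect_allele
  traits <- names(cfg$trait_baselines)
  grid <- tidyr::crossing(accession = truth$accession,
                          year = cfg$years, trait = traits)
  grid <- left_join(grid, tibble(accession = truth$accession, carrier = carrier),
                    by = "accession")
  phen <- .with_seed(cfg$seed + 2L, {
    grid |>
      mutate(
        value = cfg$trait_baselines[.data$trait] +
          cfg$year_effects[cbind(.data$trait, as.character(.data$year))] +
          ifelse(.data$carrier, cfg$effect_sizes[.data$trait], 0) +
          rnorm(dplyr::n(), 0, cfg$noise_sd[.data$trait])
      ) |>
      select("accession", "year", "trait", "value")
  })
  score <- .with_seed(cfg$seed + 3L, {
    tidyr::crossing(accession = truth$accession, year = cfg$years,
                    trait = "lodging") |>
      left_join(tibble(accession = truth$accession, carrier = carrier),
                by = "accession") |>
      mutate(value = 1 + rbinom(dplyr::n(), 8L,
                                cfg$score_p0 +
                                  ifelse(.data$carrier, cfg$score_shift, 0))) |>
      select("accession", "year", "trait", "value")
  })
  geno <- tibble(accession = truth$accession, marker = "c495",
                 allele = ifelse(carrier, "T", "G"))
  phenotype_panel(bind_rows(phen, score), geno)
}

#' Generate a random small gene model for property testing
#'
#' Draws a random exon/intron structure on a random strand with random
#' flanks, a stop-free CDS and random UTRs. Uses the ambient RNG (wrap in
#' `set.seed()` for reproducibility).
#'
#' @param n_exons Number of exons (default random 2..5).
#' @param strand `"+"` or `"-"` (default random).
#' @return A [gene_model()].
#' @export
random_gene_model <- function(n_exons = sample(2:5, 1L),
                              strand = sample(c("+", "-"), 1L)) {
  utr5e <- sample(5:30, 1L)
  utr3e <- sample(5:30, 1L)
  n_cod <- sample(25:60, 1L)
  cds <- paste0("ATG",
                paste(sample(.CODONS61, n_cod - 2L, replace = TRUE), collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  spliced <- paste0(
    paste(sample(c("A", "C", "G", "T"), utr5e, replace = TRUE), collapse = ""),
    cds,
    paste(sample(c("A", "C", "G", "T"), utr3e, replace = TRUE), collapse = "")
  )
  T_len <- nchar(spliced)
  # split the transcript into n_exons chunks of length >= 2
  if (n_exons > 1L) {
    breaks <- sort(sample(seq(2L, T_len - 2L, by = 2L), n_exons - 1L))
  } else breaks <- integer(0)
  ex_lens <- diff(c(0L, breaks, T_len))
  introns <- if (n_exons > 1L) sample(15:60, n_exons - 1L, replace = TRUE) else integer(0)
  flank5 <- sample(10:50, 1L)
  flank3 <- sample(10:50, 1L)

  pieces <- character(0)
  exon_axis <- matrix(0L, n_exons, 2L)
  pos <- flank5
  t_used <- 0L
  for (k in seq_len(n_exons)) {
    exon_axis[k, ] <- c(pos + 1L, pos + ex_lens[k])
    pieces <- c(pieces, .subseq(spliced, t_used + 1L, t_used + ex_lens[k]))
    t_used <- t_used + ex_lens[k]
    pos <- pos + ex_lens[k]
    if (k < n_exons) {
      pieces <- c(pieces, paste(sample(c("A", "C", "G", "T"), introns[k],
                                       replace = TRUE), collapse = ""))
      pos <- pos + introns[k]
    }
  }
  coding_genome <- paste0(
    paste(sample(c("A", "C", "G", "T"), flank5, replace = TRUE), collapse = ""),
    paste(pieces, collapse = ""),
    paste(sample(c("A", "C", "G", "T"), flank3, replace = TRUE), collapse = "")
  )
  L <- nchar(coding_genome)
  offset <- 100000L + sample(0:1000, 1L)
  cds_axis <- c(utr5e + 1L, utr5e + nchar(cds))
  axis_to_spliced <- function(t) {  # spliced index -> coding-axis position
    cum <- cumsum(c(0L, ex_lens))
    k <- max(which(cum < t))
    exon_axis[k, 1L] + (t - cum[k] - 1L)
  }
  j1 <- axis_to_spliced(cds_axis[1L])
  j2 <- axis_to_spliced(cds_axis[2L])
  if (strand == "+") {
    seq_plus <- coding_genome
    exons_g <- exon_axis + offset - 1L
    cds_start <- offset + j1 - 1L
    cds_end <- offset + j2 - 1L
  } else {
    seq_plus <- revcomp(coding_genome)
    exons_g <- cbind(offset + (L - exon_axis[, 2L]), offset + (L - exon_axis[, 1L]))
    cds_start <- offset + (L - j2)
    cds_end <- offset + (L - j1)
  }
  gene_model(contig = "chrSim", offset = offset, sequence = seq_plus,
             strand = strand, exons = exons_g,
             cds_start = cds_start, cds_end = cds_end)
}
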