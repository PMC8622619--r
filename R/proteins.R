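# Protein-isoform grouping and frequency-ranked allele designation.

# TRUE when a variant row lies entirely within the CDS (exonic)
.is_cds_variant <- function(model, v) {
  cv <- .coding_view(model, v$gstart, v$gend, v$ref, v$alt)
  ok <- function(g) {
    cp <- genomic_to_coding(model, g)
    cp$kind == "cds" && cp$intron_offset == 0L
  }
  ok(cv$g1) && ok(cv$g2)
}

#' Translate a haplotype's protein from its variant set
#'
#' Applies the CDS subset of a haplotype's variants to the reference coding
#' sequence and translates.
#'
#' @param model A [gene_model()].
#' @param variants A variant tibble (e.g. one element of
#'   [call_panel()]`$variants`).
#' @return List: `protein` (amino-acid string with terminal `*`, or `NA` if
#'   the CDS is frameshifted or gains an internal stop), `flag`
#'   (`"ok"`, `"frameshift"` or `"internal_stop"`).
#' @export
haplotype_protein <- function(model, variants) {
  cds <- spliced_cds(model)
  keep <- if (nrow(variants)) {
    vapply(seq_len(nrow(variants)),
           function(i) .is_cds_variant(model, variants[i, ]), TRUE)
  } else logical(0)
  alt_cds <- .apply_to_cds(model, cds, variants[keep, , drop = FALSE])
  if ((nchar(alt_cds) - nchar(cds)) %% 3L != 0L) {
    return(list(protein = NA_character_, flag = "frameshift"))
  }
  p <- translate_cds(model, alt_cds)
  body <- substr(p, 1L, nchar(p) - 1L)
  if (grepl("*", body, fixed = TRUE)) {
    return(list(protein = NA_character_, flag = "internal_stop"))
  }
  list(protein = p, flag = "ok")
}

#' Group haplotypes into protein isoforms
#'
#' Haplotypes translating to the same protein form one isoform group.
#' Groups are lettered `A`, `B`, `C`, ... in strictly decreasing order of
#' total accession frequency (ties broken lexicographically by protein
#' sequence), so `A` is always the most frequent isoform. Haplotypes whose
#' CDS cannot be translated (frameshift or internal stop) are excluded with
#' a warning.
#'
#' @param haplotypes A [call_panel()] tibble (needs `haplotype_id`, `n`,
#'   `accessions`, `variants`).
#' @param model A [gene_model()].
#' @return Tibble: `letter`, `protein`, `protein_change` (HGVS p. vs the
#'   reference), `n` (accessions), `members` (list-column of per-haplotype
#'   tibbles with ranking keys).
#' @export
group_isoforms <- function(haplotypes, model) {
  stopifnot(is.data.frame(haplotypes), inherits(model, "grf_gene_model"))
  prot <- purrr::map(haplotypes$variants, function(v) haplotype_protein(model, v))
  flags <- purrr::map_chr(prot, "flag")
  if (any(flags != "ok")) {
    warn(sprintf("excluding %d untranslatable haplotype(s): %s",
                 sum(flags != "ok"),
                 paste(haplotypes$haplotype_id[flags != "ok"], collapse = ", ")))
  }
  keep <- flags == "ok"
  ref_p <- translate_cds(model)
  df <- tibble(
    haplotype_id = haplotypes$haplotype_id[keep],
    n = haplotypes$n[keep],
    first_accession = purrr::map_chr(haplotypes$accessions[keep], 1L),
    n_variants = purrr::map_int(haplotypes$variants[keep], nrow),
    protein = purrr::map_chr(prot[keep], "protein")
  )
  groups <- df |>
    group_by(.data$protein) |>
    summarise(
      members = list(dplyr::pick("haplotype_id", "n", "first_accession",
                                 "n_variants")),
      n = sum(.data$n),
      .groups = "drop"
    ) |>
    arrange(desc(.data$n), .data$protein) |>
    mutate(letter = LETTERS[row_number()],
           protein_change = purrr::map_chr(.data$protein,
                                           function(p) .protein_diff_name(ref_p, p))) |>
    select("letter", "protein", "protein_change", "n", "members")
  groups
}

#' Designate alleles as letter.rank names
#'
#' Within each isoform group, haplotypes are ranked by decreasing accession
#' frequency (rank 1 = most frequent); the allele name is the lowercase
#' isoform letter, a dot, and the rank (`b.1`, `d.1`, ...). Frequency ties
#' are broken by the earliest-sorting member accession name, then by fewer
#' variants, so the designation is deterministic and input-order invariant.
#'
#' @param groups A [group_isoforms()] tibble.
#' @return Tibble: `haplotype_id`, `isoform_letter`, `rank`, `allele`.
#' @export
designate_alleles <- function(groups) {
  stopifnot(is.data.frame(groups))
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    m <- groups$members[[i]] |>
      arrange(desc(.data$n), .data$first_accession, .data$n_variants) |>
      mutate(rank = row_number())
    tibble(haplotype_id = m$haplotype_id,
           isoform_letter = groups$letter[i],
           rank = m$rank,
           allele = sprintf("%s.%d", tolower(groups$letter[i]), m$rank))
  })
}

#' Full designation report for a called panel
#'
#' Convenience wrapper: [group_isoforms()] + [designate_alleles()] joined
#' back onto the haplotype table.
#'
#' @inheritParams group_isoforms
#' @return The haplotype tibble with `allele`, `isoform_letter`, `rank` and
#'   `protein_change` columns added.
#' @export
designate_panel <- function(haplotypes, model) {
  groups <- group_isoforms(haplotypes, model)
  des <- designate_alleles(groups)
  chg <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    tibble(haplotype_id = groups$members[[i]]$haplotype_id,
           protein_change = groups$protein_change[i])
  })
  haplotypes |>
    left_join(des, by = "haplotype_id") |>
    left_join(chg, by = "haplotype_id")
}
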