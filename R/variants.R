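# Variant extraction, microsatellite measurement and haplotype collapsing.

#' Extract normalized, HGVS-named variants from an alignment
#'
#' Walks the alignment columns of query vs reference. Maximal runs of
#' non-matching columns become single events: one mismatching column is an
#' SNV, a pure reference gap an insertion, a pure query gap a deletion, and
#' any longer mixed run a delins. Non-adjacent mismatches (e.g. two SNVs
#' separated by one matching base) are never merged. Indels are 3'-shifted
#' on the coding strand before naming. Columns inside `mask` (by default
#' the model's microsatellite window) are excluded: microsatellite length
#' is measured separately with [measure_ssr()].
#'
#' @param model A [gene_model()].
#' @param alignment A [align_to_reference()] result (reference first), or
#'   `NULL` to align `query` internally.
#' @param query Query sequence; used when `alignment` is `NULL`.
#' @param mask Optional genomic interval(s) to exclude: a length-2 vector or
#'   a two-column matrix. Defaults to the model's `ssr_locus$window`.
#' @return A variant tibble: `gstart`, `gend`, `ref`, `alt`, `vclass`,
#'   `name_g`, `name_c`; zero rows for identical sequences.
#' @export
call_variants <- function(model, alignment = NULL, query = NULL, mask = NULL) {
  stopifnot(inherits(model, "grf_gene_model"))
  if (is.null(alignment)) {
    if (is.null(query)) abort("supply `alignment` or `query`")
    alignment <- align_to_reference(model$sequence, query)
  }
  if (is.null(mask) && !is.null(model$ssr_locus)) mask <- model$ssr_locus$window
  if (!is.null(mask)) mask <- matrix(as.integer(mask), ncol = 2L, byrow = !is.matrix(mask))

  rs <- strsplit(alignment$ref, "", fixed = TRUE)[[1]]
  qs <- strsplit(alignment$query, "", fixed = TRUE)[[1]]
  empty <- tibble(gstart = integer(0), gend = integer(0), ref = character(0),
                  alt = character(0), vclass = character(0),
                  name_g = character(0), name_c = character(0))
  diffcol <- rs != qs
  if (!any(diffcol)) return(empty)
  rp <- cumsum(rs != "-")  # reference base index consumed at/up to each column

  runs <- rle(diffcol)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- vector("list", sum(runs$values))
  oi <- 0L
  for (k in which(runs$values)) {
    i1 <- starts[k]; i2 <- ends[k]
    refseq <- paste(rs[i1:i2][rs[i1:i2] != "-"], collapse = "")
    qryseq <- paste(qs[i1:i2][qs[i1:i2] != "-"], collapse = "")
    if (refseq == "" && qryseq == "") next
    if (refseq == "") {
      prev <- rp[i1] # last reference base before the inserted columns
      if (prev < 1L || prev >= nchar(model$sequence)) next  # end-gap, unnameable
      gstart <- model$offset + prev - 1L
      gend <- gstart + 1L
      ref <- ""
    } else {
      gstart <- model$offset + min(rp[i1:i2][rs[i1:i2] != "-"]) - 1L
      gend <- model$offset + max(rp[i1:i2][rs[i1:i2] != "-"]) - 1L
      ref <- refseq
    }
    oi <- oi + 1L
    out[[oi]] <- .variant_row(model, gstart, gend, ref, qryseq)
  }
  v <- bind_rows(out[seq_len(oi)])
  if (nrow(v) == 0L) return(empty)
  if (nrow(v) && !is.null(mask)) {
    occ_s <- ifelse(v$ref == "", v$gstart + 1L, v$gstart)
    occ_e <- ifelse(v$ref == "", v$gstart, v$gend)
    hit <- rep(FALSE, nrow(v))
    for (r in seq_len(nrow(mask))) {
      hit <- hit | (occ_s <= mask[r, 2L] & occ_e >= mask[r, 1L])
    }
    v <- v[!hit, , drop = FALSE]
  }
  arrange(v, .data$gstart)
}

#' Name the protein-level consequence of coding variants
#'
#' Applies a set of CDS variants to the spliced coding sequence, translates
#' reference and alternate proteins and names the difference in HGVS p.
#' notation. Deletions inside repeat runs are placed 3'-most (C-terminal);
#' substitutions that alter consecutive residues collapse to a protein-level
#' delins.
#'
#' @param model A [gene_model()].
#' @param variant_set HGVS names (character) or a variant tibble; all
#'   variants must lie within the CDS and their combined effect must be
#'   in-frame.
#' @return The HGVS protein change, e.g. `"p.(Gln165His)"`; `"p.(=)"` when
#'   the protein is unchanged.
#' @export
name_protein_change <- function(model, variant_set) {
  stopifnot(inherits(model, "grf_gene_model"))
  if (is.character(variant_set)) {
    variant_set <- purrr::map_dfr(variant_set, function(nm) parse_hgvs(model, nm))
  }
  cds <- spliced_cds(model)
  alt_cds <- .apply_to_cds(model, cds, variant_set)
  if ((nchar(alt_cds) - nchar(cds)) %% 3L != 0L) {
    abort("frameshift variants (p. 'fs' notation) are not supported")
  }
  ref_p <- translate_cds(model, cds)
  alt_p <- translate_cds(model, alt_cds)
  .protein_diff_name(ref_p, alt_p)
}

# apply variants (plus-strand rows) within the spliced CDS coordinate space
.apply_to_cds <- function(model, cds, variants) {
  if (nrow(variants) == 0L) return(cds)
  cpos_of <- function(g) {
    cp <- genomic_to_coding(model, g)
    if (cp$kind != "cds" || cp$intron_offset != 0L) {
      abort(sprintf("variant position g.%d is not inside the CDS", g))
    }
    cp$base
  }
  rows <- purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    cv <- .coding_view(model, v$gstart, v$gend, v$ref, v$alt)
    tibble(c1 = cpos_of(cv$g1), c2 = cpos_of(cv$g2), ref = cv$ref, alt = cv$alt)
  })
  rows <- arrange(rows, .data$c1)
  s <- cds
  for (i in rev(seq_len(nrow(rows)))) {
    if (rows$ref[i] == "") {
      s <- paste0(.subseq(s, 1L, rows$c1[i]), rows$alt[i],
                  .subseq(s, rows$c2[i], nchar(s)))
    } else {
      s <- paste0(.subseq(s, 1L, rows$c1[i] - 1L), rows$alt[i],
                  .subseq(s, rows$c2[i] + 1L, nchar(s)))
    }
  }
  s
}

.AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln", E = "Glu",
  G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys", M = "Met", F = "Phe",
  P = "Pro", S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val", `*` = "Ter"
)

.aa3 <- function(x) paste(.AA3[strsplit(x, "", fixed = TRUE)[[1]]], collapse = "")

.protein_diff_name <- function(ref_p, alt_p) {
  if (identical(ref_p, alt_p)) return("p.(=)")
  r <- strsplit(ref_p, "", fixed = TRUE)[[1]]
  a <- strsplit(alt_p, "", fixed = TRUE)[[1]]
  if (length(r) == length(a)) {
    # same length: name each contiguous cluster of altered residues
    diffs <- which(r != a)
    cl <- split(diffs, cumsum(c(1L, diff(diffs) != 1L)))
    ev <- vapply(cl, function(d) {
      if (length(d) == 1L) {
        sprintf("%s%d%s", .AA3[r[d]], d, .AA3[a[d]])
      } else {
        sprintf("%s%d_%s%ddelins%s", .AA3[r[d[1L]]], d[1L],
                .AA3[r[d[length(d)]]], d[length(d)],
                paste(.AA3[a[d]], collapse = ""))
      }
    }, "")
    return(if (length(ev) == 1L) sprintf("p.(%s)", ev)
           else sprintf("p.[%s]", paste(ev, collapse = ";")))
  }
  nmin <- min(length(r), length(a))
  pre <- 0L
  while (pre < nmin && r[pre + 1L] == a[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < nmin - pre &&
         r[length(r) - suf] == a[length(a) - suf]) suf <- suf + 1L
  del <- r[seq_len(length(r) - suf)][-seq_len(pre)]
  ins <- a[seq_len(length(a) - suf)][-seq_len(pre)]
  d1 <- pre + 1L
  d2 <- length(r) - suf
  res <- function(i) paste0(.AA3[r[i]], i)
  if (length(del) == 1L && length(ins) == 1L) {
    sprintf("p.(%s%s)", res(d1), .AA3[ins])
  } else if (length(ins) == 0L) {
    if (length(del) == 1L) sprintf("p.(%sdel)", res(d1))
    else sprintf("p.(%s_%sdel)", res(d1), res(d2))
  } else if (length(del) == 0L) {
    sprintf("p.(%s_%sins%s)", res(pre), res(pre + 1L),
            paste(.AA3[ins], collapse = ""))
  } else {
    left <- res(d1)
    if (length(del) == 1L) sprintf("p.(%sdelins%s)", left, paste(.AA3[ins], collapse = ""))
    else sprintf("p.(%s_%sdelins%s)", left, res(d2), paste(.AA3[ins], collapse = ""))
  }
}

#' Measure a microsatellite tract in a query sequence
#'
#' Locates the repeat locus window in the query via the alignment to the
#' reference and measures the longest run of the repeat unit. Two runs
#' separated by fewer than one full unit (e.g. the loss of a single A in an
#' (AG)n tract) are merged and flagged `interrupted`; the tract length then
#' counts all bases from the first to the last run.
#'
#' @param model A [gene_model()] whose `ssr_locus` defines the repeat, or
#'   pass `locus` explicitly.
#' @param query Query sequence (plus strand).
#' @param locus List with `unit` (e.g. `"AG"`) and `window` (genomic
#'   interval on the reference containing the tract).
#' @param alignment Optional precomputed [align_to_reference()] result.
#' @return One-row tibble: `repeat_count` (full units), `tract_length` (nt,
#'   including interrupting bases), `interrupted`, `found` (`FALSE` when the
#'   window is absent from the query, with `tract_length` 0).
#' @export
measure_ssr <- function(model, query, locus = model$ssr_locus, alignment = NULL) {
  stopifnot(inherits(model, "grf_gene_model"))
  if (is.null(locus)) abort("no `ssr_locus` on the model and no `locus` given")
  query <- .check_sequence(query, "query")
  if (is.null(alignment)) alignment <- align_to_reference(model$sequence, query)
  rs <- strsplit(alignment$ref, "", fixed = TRUE)[[1]]
  qs <- strsplit(alignment$query, "", fixed = TRUE)[[1]]
  rp <- cumsum(rs != "-")
  w1 <- locus$window[1L] - model$offset + 1L
  w2 <- locus$window[2L] - model$offset + 1L
  cols <- which(rp >= w1 & rp <= w2)
  if (length(cols) == 0L) {
    return(tibble(repeat_count = 0L, tract_length = 0L,
                  interrupted = FALSE, found = FALSE))
  }
  wq <- paste(qs[cols][qs[cols] != "-"], collapse = "")
  u <- nchar(locus$unit)
  if (nchar(wq) < u) {
    return(tibble(repeat_count = 0L, tract_length = 0L,
                  interrupted = FALSE, found = FALSE))
  }
  # maximal pure runs of the unit
  is_unit <- vapply(seq_len(nchar(wq) - u + 1L),
                    function(i) .subseq(wq, i, i + u - 1L) == locus$unit, TRUE)
  runs <- list()
  i <- 1L
  while (i <= length(is_unit)) {
    if (is_unit[i]) {
      start <- i
      count <- 0L
      while (i <= length(is_unit) && is_unit[i]) {
        count <- count + 1L
        i <- i + u
      }
      runs[[length(runs) + 1L]] <- c(start = start, end = start + count * u - 1L,
                                     units = count)
    } else i <- i + 1L
  }
  if (length(runs) == 0L) {
    return(tibble(repeat_count = 0L, tract_length = 0L,
                  interrupted = FALSE, found = FALSE))
  }
  runs <- do.call(rbind, runs)
  # merge runs whose separation is less than one full unit
  merged <- list(runs[1L, ])
  for (k in seq_len(nrow(runs))[-1L]) {
    cur <- merged[[length(merged)]]
    gap <- runs[k, "start"] - cur["end"] - 1L
    if (gap <= u - 1L) {
      cur["end"] <- runs[k, "end"]
      cur["units"] <- cur["units"] + runs[k, "units"]
      merged[[length(merged)]] <- cur
    } else merged[[length(merged) + 1L]] <- runs[k, ]
  }
  merged <- do.call(rbind, merged)
  lens <- merged[, "end"] - merged[, "start"] + 1L
  best <- which.max(lens)
  tract_len <- as.integer(lens[best])
  units <- as.integer(merged[best, "units"])
  tibble(repeat_count = units, tract_length = tract_len,
         interrupted = tract_len != units * u, found = TRUE)
}

#' Collapse a panel of sequences into haplotypes
#'
#' Accessions with byte-identical gene-region sequences form one haplotype.
#' Haplotypes are ordered by decreasing member count, ties by the earliest
#' sorting member accession name; the grouping is invariant to input order.
#'
#' @param panel Named character vector of sequences (names = accessions) or
#'   a data frame with columns `accession` and `sequence`.
#' @return Tibble: `haplotype_id`, `n`, `accessions` (list-column),
#'   `sequence`.
#' @export
collapse_haplotypes <- function(panel) {
  if (is.data.frame(panel)) {
    seqs <- setNames(panel$sequence, panel$accession)
  } else {
    seqs <- panel
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    abort("every panel sequence must be named by its accession")
  }
  df <- tibble(accession = names(seqs), sequence = unname(seqs)) |>
    group_by(.data$sequence) |>
    summarise(n = dplyr::n(),
              accessions = list(sort(.data$accession)), .groups = "drop") |>
    mutate(first_acc = purrr::map_chr(.data$accessions, 1L)) |>
    arrange(desc(.data$n), .data$first_acc) |>
    mutate(haplotype_id = sprintf("H%02d", row_number())) |>
    select("haplotype_id", "n", "accessions", "sequence")
  df
}

#' Call variants and microsatellite lengths for a whole panel
#'
#' The one-stop pipeline over a panel of accession sequences: collapse to
#' haplotypes, align each distinct sequence to the reference, extract
#' HGVS-named variants and measure the microsatellite tract.
#'
#' @inheritParams collapse_haplotypes
#' @param model A [gene_model()].
#' @return The [collapse_haplotypes()] tibble with added columns
#'   `variants` (list of variant tibbles), `ssr_repeat_count`,
#'   `ssr_tract_length`, `ssr_interrupted`.
#' @export
call_panel <- function(model, panel) {
  haps <- collapse_haplotypes(panel)
  res <- purrr::map(haps$sequence, function(s) {
    aln <- align_to_reference(model$sequence, s)
    list(
      variants = call_variants(model, alignment = aln),
      ssr = if (is.null(model$ssr_locus)) NULL else
        measure_ssr(model, s, alignment = aln)
    )
  })
  haps$variants <- purrr::map(res, "variants")
  if (!is.null(model$ssr_locus)) {
    ssr <- bind_rows(purrr::map(res, "ssr"))
    haps$ssr_repeat_count <- ssr$repeat_count
    haps$ssr_tract_length <- ssr$tract_length
    haps$ssr_interrupted <- ssr$interrupted
  }
  haps
}

# ---- writers --------------------------------------------------------------

#' Write a variant table as minimal VCF 4.2
#'
#' Indels are converted from the package's 3'-shifted HGVS representation to
#' VCF convention: left-aligned and left-anchored on the plus strand (the
#' two representations legitimately differ; the HGVS names are carried in
#' the ID column).
#'
#' @param model A [gene_model()].
#' @param variants A variant tibble from [call_variants()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(model, variants, path) {
  row_to_vcf <- function(i) {
    v <- variants[i, ]
    gstart <- v$gstart; gend <- v$gend; ref <- v$ref; alt <- v$alt
    if (v$vclass %in% c("del", "ins")) {
      # left-align on the plus strand
      s <- model$sequence; off <- model$offset
      if (v$vclass == "del") {
        a <- gstart - off + 1L; b <- gend - off + 1L
        while (a - 1L >= 1L && .subseq(s, a - 1L, a - 1L) == .subseq(s, b, b)) {
          a <- a - 1L; b <- b - 1L
        }
        anchor <- a - 1L
        if (anchor < 1L) abort("deletion at slice start cannot be anchored")
        pos <- off + anchor - 1L
        REF <- .subseq(s, anchor, b)
        ALT <- .subseq(s, anchor, anchor)
      } else {
        p <- gstart - off + 1L
        x <- alt
        while (p >= 1L && .subseq(s, p, p) == substr(x, nchar(x), nchar(x))) {
          x <- paste0(substr(x, nchar(x), nchar(x)), substr(x, 1L, nchar(x) - 1L))
          p <- p - 1L
        }
        if (p < 1L) abort("insertion at slice start cannot be anchored")
        pos <- off + p - 1L
        REF <- .subseq(s, p, p)
        ALT <- paste0(REF, x)
      }
    } else {
      pos <- gstart
      REF <- ref
      ALT <- alt
    }
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", model$contig, pos, v$name_c, REF, ALT)
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", model$contig),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    vapply(seq_len(nrow(variants)), row_to_vcf, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-accession variant table as TSV
#'
#' @param calls A [call_panel()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(calls, path) {
  long <- calls |>
    select("haplotype_id", "accessions", "variants") |>
    tidyr::unnest_longer("accessions", values_to = "accession") |>
    tidyr::unnest("variants")
  readr::write_tsv(select(long, "accession", "haplotype_id", "name_g", "name_c",
                          "vclass"), path)
  invisible(path)
}
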