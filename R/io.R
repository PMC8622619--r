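# Plain-text IO: FASTA (via Biostrings), the annotation TSV sidecar, an
# optional GFF3 import helper, and the phenotype/genotype TSVs.

#' Write / read a gene model as FASTA + annotation TSV
#'
#' The annotation sidecar is a one-row TSV holding contig, offset, strand,
#' the exon intervals (`start-end` joined by `;`), the CDS span, the
#' promoter window and the SSR locus, so a model round-trips through plain
#' text files.
#'
#' @param model A [gene_model()].
#' @param fasta,annotation File paths.
#' @return `write_gene_model()`: the paths, invisibly; `read_gene_model()`:
#'   the reconstructed [gene_model()].
#' @export
write_gene_model <- function(model, fasta, annotation) {
  seqs <- Biostrings::DNAStringSet(setNames(
    model$sequence,
    sprintf("%s:%d-%d", model$contig, model$offset,
            model$offset + nchar(model$sequence) - 1L)
  ))
  Biostrings::writeXStringSet(seqs, fasta)
  ann <- tibble(
    contig = model$contig, offset = model$offset, strand = model$strand,
    exons = paste(sprintf("%d-%d", model$exons[, 1L], model$exons[, 2L]),
                  collapse = ";"),
    cds_start = model$cds_start, cds_end = model$cds_end,
    promoter_start = if (is.null(model$promoter_window)) NA_integer_ else model$promoter_window[1L],
    promoter_end = if (is.null(model$promoter_window)) NA_integer_ else model$promoter_window[2L],
    ssr_unit = if (is.null(model$ssr_locus)) NA_character_ else model$ssr_locus$unit,
    ssr_start = if (is.null(model$ssr_locus)) NA_integer_ else model$ssr_locus$window[1L],
    ssr_end = if (is.null(model$ssr_locus)) NA_integer_ else model$ssr_locus$window[2L]
  )
  readr::write_tsv(ann, annotation)
  invisible(c(fasta = fasta, annotation = annotation))
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(fasta, annotation) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) abort("reference FASTA must hold exactly one record")
  ann <- readr::read_tsv(annotation, show_col_types = FALSE)
  ex <- do.call(rbind, lapply(strsplit(ann$exons, ";", fixed = TRUE)[[1]],
                              function(p) as.integer(strsplit(p, "-", fixed = TRUE)[[1]])))
  gene_model(
    contig = ann$contig, offset = ann$offset,
    sequence = as.character(seqs[[1L]]), strand = ann$strand,
    exons = ex, cds_start = ann$cds_start, cds_end = ann$cds_end,
    promoter_window = if (is.na(ann$promoter_start)) NULL else
      c(ann$promoter_start, ann$promoter_end),
    ssr_locus = if (is.na(ann$ssr_unit)) NULL else
      list(unit = ann$ssr_unit,
           window = as.integer(c(ann$ssr_start, ann$ssr_end)))
  )
}

#' Import a gene model from FASTA + GFF3
#'
#' Minimal GFF3 import (via rtracklayer): only features of type `gene`,
#' `exon` and `CDS` are honored (1-based inclusive coordinates). The FASTA
#' record must cover the gene; its genomic offset is parsed from a
#' `name:start-end` header or passed explicitly.
#'
#' @param fasta Single-record FASTA of the gene region (plus strand).
#' @param gff GFF3 file.
#' @param offset Genomic coordinate of the first FASTA base; default parses
#'   a `contig:start-end` FASTA header, falling back to 1.
#' @param ... Passed on to [gene_model()] (e.g. `promoter_window`).
#' @return A [gene_model()].
#' @export
gene_model_from_gff <- function(fasta, gff, offset = NULL, ...) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("gene_model_from_gff() needs the rtracklayer package")
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) abort("reference FASTA must hold exactly one record")
  header <- names(seqs)[1L]
  if (is.null(offset)) {
    m <- regmatches(header, regexec("^(\\S+):(\\d+)-(\\d+)", header))[[1]]
    offset <- if (length(m)) as.integer(m[3L]) else 1L
  }
  gr <- as.data.frame(rtracklayer::import(gff, format = "gff3"))
  gene <- gr[gr$type == "gene", , drop = FALSE]
  exon <- gr[gr$type == "exon", , drop = FALSE]
  cds <- gr[gr$type == "CDS", , drop = FALSE]
  if (nrow(gene) != 1L) abort("GFF3 must contain exactly one gene feature")
  if (nrow(exon) < 1L || nrow(cds) < 1L) abort("GFF3 must contain exon and CDS features")
  strand <- as.character(gene$strand[1L])
  if (!strand %in% c("+", "-")) strand <- "+"
  gene_model(
    contig = as.character(gene$seqnames[1L]), offset = offset,
    sequence = as.character(seqs[[1L]]), strand = strand,
    exons = cbind(exon$start, exon$end),
    cds_start = min(cds$start), cds_end = max(cds$end),
    ...
  )
}

#' Write / read a panel of accession sequences as multi-FASTA
#'
#' @param sequences Named character vector (names = accessions).
#' @param path FASTA path.
#' @return `write_panel_fasta()`: `path` invisibly; `read_panel_fasta()`:
#'   a named character vector.
#' @export
write_panel_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Write / read a phenotype panel as two TSVs
#'
#' @param panel A [phenotype_panel()].
#' @param phenotypes,genotypes TSV paths.
#' @return `write_phenotype_panel()`: the paths invisibly;
#'   `read_phenotype_panel()`: a [phenotype_panel()].
#' @export
write_phenotype_panel <- function(panel, phenotypes, genotypes) {
  stopifnot(inherits(panel, "grf_phenotype_panel"))
  readr::write_tsv(panel$phenotypes, phenotypes)
  readr::write_tsv(panel$genotypes, genotypes)
  invisible(c(phenotypes = phenotypes, genotypes = genotypes))
}

#' @rdname write_phenotype_panel
#' @export
read_phenotype_panel <- function(phenotypes, genotypes) {
  phenotype_panel(
    readr::read_tsv(phenotypes, show_col_types = FALSE),
    readr::read_tsv(genotypes, show_col_types = FALSE)
  )
}

#' Write the simulation truth table as TSV
#'
#' Variant lists are flattened to `;`-separated HGVS names.
#'
#' @param truth The `truth` tibble from [simulate_panel()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  flat <- mutate(truth, variants = purrr::map_chr(
    .data$variants, function(v) paste(v, collapse = ";")
  ))
  readr::write_tsv(flat, path)
  invisible(path)
}
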