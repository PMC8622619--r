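# Reference gene model and genomic <-> coding (HGVS c.) coordinate maps.
#
# A gene model stores one plus-strand genomic slice (gene plus flanks), the
# exon structure in genomic orientation, the CDS span, and optionally a
# promoter window and a microsatellite locus. All genomic coordinates are
# 1-based inclusive, in the coordinate system of the source assembly; the
# first stored base sits at `offset`.

#' Construct a reference gene model
#'
#' Represents a single-gene region (gene body plus flanks) together with its
#' exon/CDS annotation, supporting conversion between genomic positions and
#' HGVS coding-style (c.) addresses. The stored sequence is always the
#' plus-strand of the assembly; for minus-strand genes all coding-coordinate
#' logic operates on the reverse complement internally.
#'
#' @param contig Contig/chromosome name (e.g. `"chr2A"`).
#' @param offset Genomic coordinate (1-based) of the first stored base.
#' @param sequence Plus-strand nucleotide sequence of the slice.
#' @param strand `"+"` or `"-"`: the strand carrying the coding sequence.
#' @param exons Two-column matrix (or data frame) of exon `[start, end]`
#'   genomic intervals, 1-based inclusive, in genomic orientation,
#'   non-overlapping and sorted.
#' @param cds_start,cds_end Genomic positions of the first base of the start
#'   codon and the last base of the stop codon *in genomic orientation*
#'   (`cds_start < cds_end` regardless of strand).
#' @param promoter_window Optional length-2 vector: a genomic interval
#'   upstream of the transcription start, not overlapping any exon.
#' @param ssr_locus Optional list with elements `unit` (repeat unit, e.g.
#'   `"AG"`) and `window` (length-2 genomic interval containing the
#'   microsatellite tract). Used by [measure_ssr()] and masked during
#'   variant calling.
#'
#' @return An object of class `grf_gene_model`.
#' @export
gene_model <- function(contig, offset, sequence, strand = c("+", "-"),
                       exons, cds_start, cds_end,
                       promoter_window = NULL, ssr_locus = NULL) {
  strand <- match.arg(strand)
  sequence <- .check_sequence(sequence)
  stopifnot(.is_count(offset), .is_count(cds_start), .is_count(cds_end))
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  if (ncol(exons) != 2L) abort("`exons` must have two columns (start, end)")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L])) abort("exon end before exon start")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    abort("exons overlap or are unsorted")
  }
  L <- nchar(sequence)
  g_last <- offset + L - 1L
  if (exons[1L, 1L] < offset || exons[nrow(exons), 2L] > g_last) {
    abort("exons fall outside the stored sequence")
  }
  in_exon <- function(g) any(g >= exons[, 1L] & g <= exons[, 2L])
  if (!in_exon(cds_start) || !in_exon(cds_end)) {
    abort("cds_start and cds_end must fall inside exons")
  }
  if (cds_start >= cds_end) abort("cds_start must be < cds_end (genomic orientation)")
  if (!is.null(promoter_window)) {
    promoter_window <- as.integer(promoter_window)
    if (length(promoter_window) != 2L || promoter_window[1L] > promoter_window[2L]) {
      abort("`promoter_window` must be an increasing length-2 interval")
    }
    if (any(promoter_window[1L] <= exons[, 2L] & promoter_window[2L] >= exons[, 1L])) {
      abort("`promoter_window` overlaps an exon")
    }
  }
  model <- structure(
    list(
      contig = as.character(contig), offset = as.integer(offset),
      sequence = sequence, strand = strand, exons = exons,
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
      promoter_window = promoter_window, ssr_locus = ssr_locus
    ),
    class = "grf_gene_model"
  )
  cds <- spliced_cds(model)
  if (nchar(cds) %% 3L != 0L) abort("spliced CDS length is not a multiple of 3")
  if (substr(cds, 1L, 3L) != "ATG") abort("spliced CDS does not begin with ATG")
  if (!substr(cds, nchar(cds) - 2L, nchar(cds)) %in% c("TAA", "TAG", "TGA")) {
    abort("spliced CDS does not end with a stop codon")
  }
  model
}

#' @export
print.grf_gene_model <- function(x, ...) {
  cat(sprintf(
    "<grf_gene_model> %s:%d-%d (%s), %d exons, CDS %d nt (%d aa)\n",
    x$contig, x$offset, x$offset + nchar(x$sequence) - 1L, x$strand,
    nrow(x$exons), cds_length(x), cds_length(x) / 3L - 1L
  ))
  invisible(x)
}

# ---- internal coordinate frame -------------------------------------------
# Everything is computed on the "coding axis": slice indices for "+" genes,
# reversed indices for "-" genes, so that position 1 is the 5'-most stored
# base of the coding strand.

.frame <- function(model) {
  L <- nchar(model$sequence)
  to_slice <- function(g) g - model$offset + 1L
  if (model$strand == "+") {
    ex <- cbind(to_slice(model$exons[, 1L]), to_slice(model$exons[, 2L]))
    seq_c <- model$sequence
    j_cds_s <- to_slice(model$cds_start)
    j_cds_e <- to_slice(model$cds_end)
  } else {
    ex <- cbind(L + 1L - to_slice(model$exons[, 2L]), L + 1L - to_slice(model$exons[, 1L]))
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    seq_c <- revcomp(model$sequence)
    j_cds_s <- L + 1L - to_slice(model$cds_end)
    j_cds_e <- L + 1L - to_slice(model$cds_start)
  }
  lens <- ex[, 2L] - ex[, 1L] + 1L
  cum0 <- cumsum(c(0L, lens))[seq_len(nrow(ex))]  # spliced bases before exon k
  spliced_of <- function(j) {                     # j must be exonic
    k <- which(j >= ex[, 1L] & j <= ex[, 2L])
    cum0[k] + (j - ex[k, 1L] + 1L)
  }
  list(
    L = L, ex = ex, seq_c = seq_c, cum0 = cum0, lens = lens,
    T_len = sum(lens),
    S = spliced_of(j_cds_s), E = spliced_of(j_cds_e),
    spliced_of = spliced_of,
    axis_of = function(t) {                       # inverse of spliced_of
      k <- max(which(cum0 < t))
      ex[k, 1L] + (t - cum0[k] - 1L)
    },
    g_of_axis = function(j) {
      if (model$strand == "+") model$offset + j - 1L else model$offset + (L - j)
    },
    axis_of_g = function(g) {
      i <- g - model$offset + 1L
      if (model$strand == "+") i else L + 1L - i
    }
  )
}

# spliced position -> cds / utr coding address (kind, base or utr_offset)
.spliced_to_address <- function(t, fr) {
  if (t < fr$S) list(kind = "utr5", utr_offset = -(fr$S - t))
  else if (t > fr$E) list(kind = "utr3", utr_offset = t - fr$E)
  else list(kind = "cds", base = t - fr$S + 1L)
}

#' Convert a genomic position to an HGVS coding-style address
#'
#' CDS bases are numbered `1..L` along the spliced coding strand; 5'UTR (and
#' upstream flank) bases count back from the A of the ATG as `c.-N`; 3'UTR
#' (and downstream flank) bases count forward from the first base after the
#' stop codon as `c.*N`; intronic bases are addressed from the nearest exon
#' edge (`c.N+M` / `c.N-M`, midpoint ties to the 5' edge).
#'
#' @param model A [gene_model()].
#' @param gpos A single genomic position inside the stored slice.
#' @return A `grf_coding_position`; render it with `format()` or
#'   `as.character()`, parse the text form back with
#'   [parse_coding_position()].
#' @seealso [coding_to_genomic()] for the inverse.
#' @export
genomic_to_coding <- function(model, gpos) {
  stopifnot(inherits(model, "grf_gene_model"), .is_count(gpos))
  L <- nchar(model$sequence)
  if (gpos < model$offset || gpos > model$offset + L - 1L) {
    abort(sprintf("position %d outside stored sequence [%d, %d]",
                  gpos, model$offset, model$offset + L - 1L))
  }
  fr <- .frame(model)
  j <- fr$axis_of_g(as.integer(gpos))
  ex <- fr$ex
  n_ex <- nrow(ex)
  if (j < ex[1L, 1L]) {            # upstream flank: continue c.-N linearly
    return(new_coding_position("utr5", utr_offset = -((fr$S - 1L) + (ex[1L, 1L] - j))))
  }
  if (j > ex[n_ex, 2L]) {          # downstream flank: continue c.*N linearly
    return(new_coding_position("utr3", utr_offset = (fr$T_len - fr$E) + (j - ex[n_ex, 2L])))
  }
  k <- which(j >= ex[, 1L] & j <= ex[, 2L])
  if (length(k) == 1L) {           # exonic
    ad <- .spliced_to_address(fr$spliced_of(j), fr)
    return(new_coding_position(ad$kind, base = ad$base, utr_offset = ad$utr_offset))
  }
  k <- max(which(ex[, 2L] < j))    # intronic, between exon k and k+1
  d5 <- j - ex[k, 2L]
  d3 <- ex[k + 1L, 1L] - j
  if (d5 <= d3) {
    ad <- .spliced_to_address(fr$spliced_of(ex[k, 2L]), fr)
    off <- d5
  } else {
    ad <- .spliced_to_address(fr$spliced_of(ex[k + 1L, 1L]), fr)
    off <- -d3
  }
  new_coding_position("intron", base = ad$base, utr_offset = ad$utr_offset,
                      intron_offset = off)
}

#' Convert an HGVS coding-style address to a genomic position
#'
#' Inverse of [genomic_to_coding()]: accepts a `grf_coding_position` or its
#' text form (e.g. `"495"`, `"-140"`, `"*8"`, `"325+169"`, `"326-39"`).
#'
#' @param model A [gene_model()].
#' @param cpos A `grf_coding_position` or a string to pass through
#'   [parse_coding_position()].
#' @return A genomic position (integer).
#' @export
coding_to_genomic <- function(model, cpos) {
  stopifnot(inherits(model, "grf_gene_model"))
  if (is.character(cpos)) cpos <- parse_coding_position(cpos)
  stopifnot(inherits(cpos, "grf_coding_position"))
  fr <- .frame(model)
  ex <- fr$ex
  n_ex <- nrow(ex)
  anchor_t <- function() {
    if (!is.na(cpos$base)) {
      if (cpos$base < 1L || cpos$base > (fr$E - fr$S + 1L)) {
        abort(sprintf("CDS position %d outside CDS (length %d)", cpos$base, fr$E - fr$S + 1L))
      }
      fr$S - 1L + cpos$base
    } else if (cpos$utr_offset < 0L) fr$S + cpos$utr_offset
    else fr$E + cpos$utr_offset
  }
  j <- if (cpos$kind == "intron") {
    t <- anchor_t()
    if (t < 1L || t > fr$T_len) abort("intron anchor outside transcript")
    fr$axis_of(t) + cpos$intron_offset
  } else {
    t <- anchor_t()
    if (t >= 1L && t <= fr$T_len) fr$axis_of(t)
    else if (t < 1L) ex[1L, 1L] - (1L - t)              # upstream flank
    else ex[n_ex, 2L] + (t - fr$T_len)                  # downstream flank
  }
  if (j < 1L || j > fr$L) {
    abort(sprintf("coding address c.%s maps outside the stored sequence", format(cpos)))
  }
  fr$g_of_axis(j)
}

#' Codon index of a CDS position
#'
#' @param cpos CDS position(s), 1-based along the spliced coding sequence.
#' @return Codon (protein residue) index: `floor((cpos - 1) / 3) + 1`.
#' @export
#' @examples
#' cds_to_protein_position(495) # 165
cds_to_protein_position <- function(cpos) {
  if (!is.numeric(cpos) || any(is.na(cpos)) || any(cpos <= 0) ||
      any(cpos != as.integer(cpos))) {
    abort("`cpos` must be positive integer CDS position(s)")
  }
  as.integer((cpos - 1L) %/% 3L + 1L)
}

# ---- accessors ------------------------------------------------------------

#' Spliced coding sequence of a gene model
#' @param model A [gene_model()].
#' @return The spliced CDS (coding strand), `ATG ... stop`.
#' @export
spliced_cds <- function(model) {
  fr <- .frame(model)
  tr <- paste(
    vapply(seq_len(nrow(fr$ex)),
           function(k) .subseq(fr$seq_c, fr$ex[k, 1L], fr$ex[k, 2L]), ""),
    collapse = ""
  )
  .subseq(tr, fr$S, fr$E)
}

#' @rdname spliced_cds
#' @export
cds_length <- function(model) nchar(spliced_cds(model))

#' Translate the (spliced) CDS of a gene model
#' @param model A [gene_model()].
#' @param cds Optionally, an alternative CDS string to translate instead.
#' @return Amino-acid string including the terminal `*`.
#' @export
translate_cds <- function(model, cds = NULL) {
  if (is.null(cds)) cds <- spliced_cds(model)
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

# reference base(s) at genomic interval
ref_base <- function(model, gstart, gend = gstart) {
  .subseq(model$sequence, gstart - model$offset + 1L, gend - model$offset + 1L)
}
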