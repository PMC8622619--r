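# HGVS coding-position and variant-name machinery.
#
# Internal variant representation (one row per variant):
#   gstart, gend : genomic interval, 1-based inclusive; for pure insertions
#                  the flanking base pair (gend == gstart + 1)
#   ref, alt     : plus-strand nucleotide strings ("" allowed on one side)
#   vclass       : SNV | del | ins | delins
#   name_g       : "contig:g...." text
#   name_c       : "c...." text (coding strand)
# Indels are 3'-shifted on the coding strand before naming.

# ---- coding positions -----------------------------------------------------

new_coding_position <- function(kind, base = NA_integer_, utr_offset = NA_integer_,
                                intron_offset = 0L) {
  if (is.null(base) || length(base) == 0L) base <- NA_integer_
  if (is.null(utr_offset) || length(utr_offset) == 0L) utr_offset <- NA_integer_
  structure(
    list(kind = kind, base = as.integer(base),
         utr_offset = as.integer(utr_offset),
         intron_offset = as.integer(intron_offset)),
    class = "grf_coding_position"
  )
}

#' @export
format.grf_coding_position <- function(x, ...) {
  anchor <- if (!is.na(x$base)) {
    as.character(x$base)
  } else if (x$utr_offset < 0L) {
    as.character(x$utr_offset)
  } else {
    paste0("*", x$utr_offset)
  }
  if (x$kind == "intron") paste0(anchor, sprintf("%+d", x$intron_offset)) else anchor
}

#' @export
as.character.grf_coding_position <- function(x, ...) format(x)

#' @export
print.grf_coding_position <- function(x, ...) {
  cat(sprintf("<coding position> c.%s (%s)\n", format(x), x$kind))
  invisible(x)
}

#' Parse the text form of an HGVS coding-style position
#'
#' Accepts the four addressing styles: CDS (`"495"`), 5'UTR (`"-140"`),
#' 3'UTR (`"*8"`) and intronic (`"325+169"`, `"326-39"`, `"-85+3"`).
#' Rendering with `format()` then parsing is the identity.
#'
#' @param text A single position string (without the `c.` prefix).
#' @return A `grf_coding_position`.
#' @export
parse_coding_position <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^(\\*?-?[0-9]+)(?:([+-])([0-9]+))?$", text))[[1]]
  if (length(m) == 0L) abort(sprintf("cannot parse coding position '%s'", text))
  anchor <- m[2]
  off <- if (m[3] == "") 0L else as.integer(paste0(m[3], m[4]))
  kind <- if (off != 0L) "intron" else NULL
  if (startsWith(anchor, "*")) {
    u <- as.integer(sub("^\\*", "", anchor))
    if (u <= 0L) abort(sprintf("invalid 3'UTR position '%s'", text))
    new_coding_position(kind %||% "utr3", utr_offset = u, intron_offset = off)
  } else {
    a <- as.integer(anchor)
    if (a < 0L) {
      new_coding_position(kind %||% "utr5", utr_offset = a, intron_offset = off)
    } else if (a == 0L) {
      abort("there is no coding position 0")
    } else {
      new_coding_position(kind %||% "cds", base = a, intron_offset = off)
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- naming ---------------------------------------------------------------

.vclass <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
  else if (nchar(alt) == 0L) "del"
  else if (nchar(ref) == 0L) "ins"
  else "delins"
}

# coding-strand view of a plus-strand variant: interval endpoints in coding
# order and ref/alt in coding orientation
.coding_view <- function(model, gstart, gend, ref, alt) {
  if (model$strand == "+") {
    list(g1 = gstart, g2 = gend, ref = ref, alt = alt)
  } else {
    list(g1 = gend, g2 = gstart,
         ref = if (nchar(ref)) revcomp(ref) else "",
         alt = if (nchar(alt)) revcomp(alt) else "")
  }
}

# name_g / name_c / vclass for one normalized variant
hgvs_names <- function(model, gstart, gend, ref, alt) {
  vclass <- .vclass(ref, alt)
  gtxt <- switch(vclass,
    SNV    = sprintf("g.%d%s>%s", gstart, ref, alt),
    del    = if (gstart == gend) sprintf("g.%ddel", gstart)
             else sprintf("g.%d_%ddel", gstart, gend),
    ins    = sprintf("g.%d_%dins%s", gstart, gend, alt),
    delins = if (gstart == gend) sprintf("g.%ddelins%s", gstart, alt)
             else sprintf("g.%d_%ddelins%s", gstart, gend, alt)
  )
  cv <- .coding_view(model, gstart, gend, ref, alt)
  c1 <- format(genomic_to_coding(model, cv$g1))
  c2 <- format(genomic_to_coding(model, cv$g2))
  ctxt <- switch(vclass,
    SNV    = sprintf("c.%s%s>%s", c1, cv$ref, cv$alt),
    del    = if (identical(c1, c2)) sprintf("c.%sdel", c1)
             else sprintf("c.%s_%sdel", c1, c2),
    ins    = sprintf("c.%s_%sins%s", c1, c2, cv$alt),
    delins = if (identical(c1, c2)) sprintf("c.%sdelins%s", c1, cv$alt)
             else sprintf("c.%s_%sdelins%s", c1, c2, cv$alt)
  )
  list(name_g = paste0(model$contig, ":", gtxt), name_c = ctxt, vclass = vclass)
}

# 3'-shift an indel on the coding strand; returns updated plus-strand fields
.shift3 <- function(model, gstart, gend, ref, alt) {
  vclass <- .vclass(ref, alt)
  if (!vclass %in% c("del", "ins")) {
    return(list(gstart = gstart, gend = gend, ref = ref, alt = alt))
  }
  fr <- .frame(model)
  if (vclass == "del") {
    cv <- .coding_view(model, gstart, gend, ref, alt)
    a <- fr$axis_of_g(cv$g1); b <- fr$axis_of_g(cv$g2)
    while (b + 1L <= fr$L &&
           .subseq(fr$seq_c, b + 1L, b + 1L) == .subseq(fr$seq_c, a, a)) {
      a <- a + 1L; b <- b + 1L
    }
    g1 <- fr$g_of_axis(a); g2 <- fr$g_of_axis(b)
    gstart <- min(g1, g2); gend <- max(g1, g2)
    ref <- ref_base(model, gstart, gend)
    list(gstart = gstart, gend = gend, ref = ref, alt = "")
  } else {
    cv <- .coding_view(model, gstart, gend, ref, alt)
    p <- fr$axis_of_g(cv$g1)          # coding-axis left flank
    x <- cv$alt
    while (p + 1L <= fr$L && .subseq(fr$seq_c, p + 1L, p + 1L) == substr(x, 1L, 1L)) {
      x <- paste0(substr(x, 2L, nchar(x)), substr(x, 1L, 1L))
      p <- p + 1L
    }
    if (p + 1L > fr$L) abort("insertion shifted past the stored sequence")
    g1 <- fr$g_of_axis(p); g2 <- fr$g_of_axis(p + 1L)
    list(gstart = min(g1, g2), gend = max(g1, g2),
         ref = "", alt = if (model$strand == "+") x else revcomp(x))
  }
}

.variant_row <- function(model, gstart, gend, ref, alt, normalize = TRUE) {
  if (normalize) {
    sh <- .shift3(model, gstart, gend, ref, alt)
    gstart <- sh$gstart; gend <- sh$gend; ref <- sh$ref; alt <- sh$alt
  }
  nm <- hgvs_names(model, gstart, gend, ref, alt)
  tibble(
    gstart = as.integer(gstart), gend = as.integer(gend),
    ref = ref, alt = alt, vclass = nm$vclass,
    name_g = nm$name_g, name_c = nm$name_c
  )
}

# ---- parsing variant names ------------------------------------------------

#' Parse an HGVS variant name against a gene model
#'
#' Accepts genomic (`"g.687048627G>C"`, optionally with a `contig:` prefix)
#' and coding (`"c.495G>T"`, `"c.126_134del"`, `"c.325+32_325+33insTCC"`,
#' `"c.-102_-91del"`, ...) substitution, deletion, insertion and delins
#' names. The abbreviated second intron address (`"c.325+32_+33insTCC"`) is
#' accepted as an alias of the full form.
#'
#' @param model A [gene_model()].
#' @param name A single HGVS variant name.
#' @return A one-row variant tibble (`gstart`, `gend`, `ref`, `alt`,
#'   `vclass`, `name_g`, `name_c`) with plus-strand `ref`/`alt`.
#' @export
parse_hgvs <- function(model, name) {
  stopifnot(inherits(model, "grf_gene_model"), is.character(name), length(name) == 1L)
  txt <- sub("^[A-Za-z0-9_.]+:", "", name)
  m <- regmatches(txt, regexec(
    "^([cg])\\.([^ACGTN>]+?)(?:([ACGTN])>([ACGTN])|delins([ACGTN]+)|del([ACGTN]*)|ins([ACGTN]+))$",
    txt))[[1]]
  if (length(m) == 0L) abort(sprintf("cannot parse HGVS name '%s'", name))
  space <- m[2]
  postxt <- m[3]
  parts <- strsplit(postxt, "_", fixed = TRUE)[[1]]
  if (length(parts) > 2L) abort(sprintf("cannot parse interval in '%s'", name))

  pos_of <- function(tok, anchor = NULL) {
    if (space == "g") return(as.integer(tok))
    cp <- if (!is.null(anchor) && grepl("^[+-][0-9]+$", tok) &&
              anchor$intron_offset != 0L) {
      # abbreviated alias: "c.325+32_+33..." inherits the first anchor
      a <- anchor
      a$intron_offset <- as.integer(tok)
      a$kind <- "intron"
      a
    } else {
      parse_coding_position(tok)
    }
    list(g = coding_to_genomic(model, cp), cp = cp)
  }

  if (space == "g") {
    g1 <- as.integer(parts[1]); g2 <- if (length(parts) == 2L) as.integer(parts[2]) else g1
  } else {
    p1 <- pos_of(parts[1])
    p2 <- if (length(parts) == 2L) pos_of(parts[2], anchor = p1$cp) else p1
    g1 <- p1$g; g2 <- p2$g
  }
  gstart <- min(g1, g2); gend <- max(g1, g2)

  flip <- function(x) if (space == "c" && model$strand == "-") revcomp(x) else x
  if (m[4] != "") {                                   # substitution
    if (gstart != gend) abort(sprintf("substitution with interval in '%s'", name))
    ref <- flip(m[4]); alt <- flip(m[5])
    have <- ref_base(model, gstart)
    if (have != ref) {
      abort(sprintf("reference mismatch for '%s': model has %s", name, have))
    }
    return(.variant_row(model, gstart, gend, ref, alt, normalize = FALSE))
  }
  if (m[6] != "") {                                   # delins
    return(.variant_row(model, gstart, gend, ref_base(model, gstart, gend),
                        flip(m[6]), normalize = FALSE))
  }
  if (m[8] != "") {                                   # insertion between flanks
    if (gend != gstart + 1L) abort(sprintf("insertion flanks not adjacent in '%s'", name))
    return(.variant_row(model, gstart, gend, "", flip(m[8])))
  }
  # deletion (optional explicit deleted sequence)
  ref <- ref_base(model, gstart, gend)
  if (m[7] != "" && flip(m[7]) != ref) {
    abort(sprintf("deleted sequence in '%s' does not match the reference", name))
  }
  .variant_row(model, gstart, gend, ref, "")
}

# ---- applying variants ----------------------------------------------------

#' Apply variants to the reference sequence of a gene model
#'
#' @param model A [gene_model()].
#' @param variants Either a character vector of HGVS names (parsed with
#'   [parse_hgvs()]) or a variant tibble with `gstart`, `gend`, `ref`, `alt`.
#' @return The alternate plus-strand sequence (character scalar).
#' @export
apply_variants <- function(model, variants) {
  stopifnot(inherits(model, "grf_gene_model"))
  if (is.character(variants)) {
    variants <- purrr::map_dfr(variants, function(nm) parse_hgvs(model, nm))
  }
  if (nrow(variants) == 0L) return(model$sequence)
  v <- arrange(variants, .data$gstart)
  # insertions occupy no reference base; overlap checks use the occupied span
  occ_s <- ifelse(v$ref == "", v$gstart + 1L, v$gstart)
  occ_e <- ifelse(v$ref == "", v$gstart, v$gend)
  if (nrow(v) > 1L && any(occ_s[-1L] <= occ_e[-nrow(v)])) {
    abort("overlapping variants in one allele")
  }
  s <- model$sequence
  for (i in rev(seq_len(nrow(v)))) {
    si <- v$gstart[i] - model$offset + 1L
    ei <- v$gend[i] - model$offset + 1L
    if (v$ref[i] == "") {
      # insertion between flanking pair (si, ei)
      s <- paste0(.subseq(s, 1L, si), v$alt[i], .subseq(s, ei, nchar(s)))
    } else {
      if (.subseq(s, si, ei) != v$ref[i]) abort("variant ref does not match model sequence")
      s <- paste0(.subseq(s, 1L, si - 1L), v$alt[i], .subseq(s, ei + 1L, nchar(s)))
    }
  }
  s
}
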