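# In-silico molecular markers: PCR product prediction, CAPS restriction
# digestion with staggered-cut (type IIS) enzymes, and SSR fragment
# genotyping with homoeolog size bins.

#' Marker definitions
#'
#' Constructors for the three marker types: a PCR primer pair, a
#' restriction enzyme with staggered cut offsets (e.g. SfaN I,
#' `GCATC(5/9)`: recognition `GCATC`, top-strand cut 5 nt and bottom-strand
#' cut 9 nt downstream of the recognition 3' end), and disjoint SSR
#' product-size bins keyed by locus.
#'
#' @param name Marker/enzyme name.
#' @param forward,reverse Primer sequences, 5'->3', length >= 15.
#' @param max_product Maximum product length reported by [insilico_pcr()].
#' @return An object of class `grf_primer_pair`, `grf_enzyme` or
#'   `grf_ssr_bins` respectively.
#' @export
primer_pair <- function(name, forward, reverse, max_product = 2000L) {
  forward <- .check_sequence(forward, "forward")
  reverse <- .check_sequence(reverse, "reverse")
  if (nchar(forward) < 15L || nchar(reverse) < 15L) {
    abort("primers must be at least 15 nt long")
  }
  if (max_product <= nchar(forward) + nchar(reverse)) {
    abort("`max_product` must exceed the combined primer length")
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 max_product = as.integer(max_product)),
            class = "grf_primer_pair")
}

#' @rdname primer_pair
#' @param recognition Recognition sequence (searched on both strands).
#' @param cut_top,cut_bottom Cut offsets (nt, >= 0) downstream of the
#'   recognition site's 3' end on the recognition-carrying strand and the
#'   opposite strand.
#' @export
restriction_enzyme <- function(name, recognition, cut_top, cut_bottom) {
  recognition <- .check_sequence(recognition, "recognition")
  stopifnot(.is_count(cut_top), .is_count(cut_bottom), cut_top >= 0, cut_bottom >= 0)
  structure(list(name = name, recognition = recognition,
                 cut_top = as.integer(cut_top), cut_bottom = as.integer(cut_bottom)),
            class = "grf_enzyme")
}

#' @rdname primer_pair
#' @param ... Named length-2 numeric vectors, one `c(min, max)` product-size
#'   interval per locus; intervals must be pairwise disjoint.
#' @export
ssr_bins <- function(...) {
  b <- list(...)
  if (length(b) == 0L || is.null(names(b)) || any(names(b) == "")) {
    abort("supply named `c(min, max)` intervals")
  }
  tab <- purrr::map_dfr(names(b), function(nm) {
    iv <- b[[nm]]
    if (length(iv) != 2L || iv[1L] > iv[2L]) abort("each bin must be c(min, max)")
    tibble(locus = nm, min = as.integer(iv[1L]), max = as.integer(iv[2L]))
  })
  tab <- arrange(tab, .data$min)
  if (nrow(tab) > 1L && any(tab$min[-1L] <= tab$max[-nrow(tab)])) {
    abort("SSR bins overlap")
  }
  structure(tab, class = c("grf_ssr_bins", class(tab)))
}

# match sites of `primer` in `template`; the primer's 3'-terminal 5-mer must
# match exactly, internal positions may carry up to `max_mismatch` mismatches
.match_sites <- function(template, primer, max_mismatch = 0L,
                         three_prime = c("right", "left")) {
  three_prime <- match.arg(three_prime)
  if (max_mismatch == 0L) return(.find_all(template, primer))
  np <- nchar(primer)
  nt <- nchar(template)
  if (nt < np) return(integer(0))
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  tc <- strsplit(template, "", fixed = TRUE)[[1]]
  anchor <- if (three_prime == "right") (np - 4L):np else 1:5
  out <- integer(0)
  for (s in 1:(nt - np + 1L)) {
    w <- tc[s:(s + np - 1L)]
    if (any(w[anchor] != pc[anchor])) next
    if (sum(w != pc) <= max_mismatch) out <- c(out, s)
  }
  out
}

#' Predict PCR products in silico
#'
#' Searches both template strands: a product is reported wherever the
#' forward primer matches one strand and the reverse primer the other,
#' facing inwards, within `max_product`. Matching is exact by default; with
#' `max_mismatch > 0` internal mismatches are tolerated but the 3'-terminal
#' 5-mer must match exactly. Product length counts both primer footprints
#' inclusively. All qualifying primer placements are reported (the caller
#' decides uniqueness); no product is an empty result, not an error.
#'
#' @param template Template sequence.
#' @param primers A [primer_pair()].
#' @param max_mismatch Allowed internal mismatches per primer (default 0).
#' @return Tibble: `start`, `end` (template coordinates of the product),
#'   `length`, `strand` (strand carrying the forward primer), `sequence`.
#' @export
insilico_pcr <- function(template, primers, max_mismatch = 0L) {
  template <- .check_sequence(template, "template")
  stopifnot(inherits(primers, "grf_primer_pair"))
  L <- nchar(template)
  one_strand <- function(tpl) {
    f <- .match_sites(tpl, primers$forward, max_mismatch, "right")
    r <- .match_sites(tpl, revcomp(primers$reverse), max_mismatch, "left")
    out <- list()
    for (fs in f) {
      fe <- fs + nchar(primers$forward) - 1L
      for (rs in r) {
        re <- rs + nchar(primers$reverse) - 1L
        len <- re - fs + 1L
        if (rs > fe && len <= primers$max_product) {
          out[[length(out) + 1L]] <- c(start = fs, end = re, length = len)
        }
      }
    }
    if (length(out) == 0L) {
      tibble(start = integer(0), end = integer(0), length = integer(0))
    } else {
      as_tibble(do.call(rbind, out))
    }
  }
  plus <- one_strand(template) |> mutate(strand = "+")
  minus <- one_strand(revcomp(template)) |>
    mutate(start2 = L - .data$end + 1L, end2 = L - .data$start + 1L,
           start = .data$start2, end = .data$end2, strand = "-") |>
    select("start", "end", "length", "strand")
  res <- bind_rows(plus, minus) |> arrange(.data$start)
  res$sequence <- vapply(seq_len(nrow(res)), function(i) {
    s <- .subseq(template, res$start[i], res$end[i])
    if (res$strand[i] == "-") revcomp(s) else s
  }, "")
  res
}

#' Digest an amplicon with a restriction enzyme
#'
#' Every occurrence of the recognition sequence on either strand yields one
#' double-strand cut. Fragment boundaries follow the chosen strand's cut
#' positions (default top strand: recognition 3' end + `cut_top` for
#' top-strand sites; for a staggered cutter like SfaN I (5/9) the
#' bottom-strand convention shifts fragment sizes by the stagger). Cut
#' positions falling beyond the amplicon are ignored with a warning (the
#' enzyme would not cleave a truncated site). Fragment lengths always sum
#' to the amplicon length; with no site the amplicon is returned intact.
#'
#' @param amplicon Amplicon sequence.
#' @param enzyme A [restriction_enzyme()].
#' @param convention `"top"` or `"bottom"`: which strand's cut positions
#'   define the reported fragment lengths.
#' @return Sorted integer vector of fragment lengths.
#' @export
caps_digest <- function(amplicon, enzyme, convention = c("top", "bottom")) {
  amplicon <- .check_sequence(amplicon, "amplicon")
  convention <- match.arg(convention)
  stopifnot(inherits(enzyme, "grf_enzyme"))
  L <- nchar(amplicon)
  k <- nchar(enzyme$recognition)
  off_plus <- if (convention == "top") enzyme$cut_top else enzyme$cut_bottom
  off_minus <- if (convention == "top") enzyme$cut_bottom else enzyme$cut_top
  cuts <- integer(0)
  for (s in .find_all(amplicon, enzyme$recognition)) {
    cp <- s + k - 1L + off_plus          # last base of the left fragment
    if (cp >= 1L && cp < L) cuts <- c(cuts, cp) else {
      warn(sprintf("%s site at %d: cut position beyond amplicon, ignored",
                   enzyme$name, s))
    }
  }
  rcrec <- revcomp(enzyme$recognition)
  for (s in .find_all(amplicon, rcrec)) {
    # recognition on the bottom strand: its 3' end faces left in top coords
    cp <- s - off_minus - 1L
    if (cp >= 1L && cp < L) cuts <- c(cuts, cp) else {
      warn(sprintf("%s site (bottom strand) at %d: cut position beyond amplicon, ignored",
                   enzyme$name, s))
    }
  }
  sort(as.integer(diff(c(0L, sort(unique(cuts)), L))))
}

#' Assign SSR products to locus size bins
#'
#' @param products Numeric vector of product lengths (bp).
#' @param bins A [ssr_bins()] table of disjoint intervals.
#' @return Tibble: `product`, `locus` (`NA` for products falling outside
#'   every bin).
#' @export
ssr_genotype <- function(products, bins) {
  stopifnot(inherits(bins, "grf_ssr_bins"), is.numeric(products))
  locus <- vapply(products, function(p) {
    hit <- which(p >= bins$min & p <= bins$max)
    if (length(hit) == 1L) bins$locus[hit] else NA_character_
  }, "")
  tibble(product = products, locus = locus)
}

#' The published marker set for the GRF3-2A locus
#'
#' The three diagnostic assays: the GRF3A-Q42 primer pair flanking the 9-nt
#' polyglutamine deletion (products 344 bp wild type / 335 bp deletion),
#' the GRF3A-Q165 pair (454 bp) whose product gains an SfaN I site on the
#' c.495 T allele (201 + 253 bp fragments, top-strand convention), and the
#' subgenome-shared 5'UTR SSR pair with non-overlapping 2A (230-282 bp) and
#' 2D (211-223 bp) size bins.
#'
#' @return Named list: `q42`, `q165` ([primer_pair()]s), `sfani`
#'   ([restriction_enzyme()]), `ssr` ([primer_pair()]), `bins`
#'   ([ssr_bins()]).
#' @export
grf_marker_set <- function() {
  list(
    q42 = primer_pair("GRF3A-Q42", .G$q42_f, .G$q42_r),
    q165 = primer_pair("GRF3A-Q165", .G$q165_f, .G$q165_r),
    sfani = restriction_enzyme("SfaNI", "GCATC", 5L, 9L),
    ssr = primer_pair("GRF3-2AD-SSR", .G$ssr_f, .G$ssr_r),
    bins = ssr_bins(`2A` = c(230L, 282L), `2D` = c(211L, 223L))
  )
}

#' Score the diagnostic markers across a panel of sequences
#'
#' Runs the three assays of [grf_marker_set()] on each accession sequence:
#' the Q42 product length, the c.495 CAPS call (T when the Q165 amplicon is
#' cleaved by SfaN I, G when intact), and the SSR product size with its
#' homoeolog bin.
#'
#' @param sequences Named character vector of accession sequences.
#' @param markers A marker set as returned by [grf_marker_set()].
#' @return Tibble: `accession`, `q42_bp`, `c495_allele`, `caps_fragments`
#'   (list-column), `ssr_bp`, `ssr_locus`.
#' @export
genotype_markers <- function(sequences, markers = grf_marker_set()) {
  purrr::map_dfr(names(sequences), function(acc) {
    s <- sequences[[acc]]
    q42 <- insilico_pcr(s, markers$q42)
    q165 <- insilico_pcr(s, markers$q165)
    frags <- if (nrow(q165)) caps_digest(q165$sequence[1L], markers$sfani) else integer(0)
    ssr <- insilico_pcr(s, markers$ssr)
    bin <- if (nrow(ssr)) ssr_genotype(ssr$length[1L], markers$bins)$locus else NA_character_
    tibble(
      accession = acc,
      q42_bp = if (nrow(q42)) q42$length[1L] else NA_integer_,
      c495_allele = if (length(frags) == 0L) NA_character_
                    else if (length(frags) > 1L) "T" else "G",
      caps_fragments = list(frags),
      ssr_bp = if (nrow(ssr)) ssr$length[1L] else NA_integer_,
      ssr_locus = bin
    )
  })
}
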