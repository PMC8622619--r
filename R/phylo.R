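# SNP-only haplotype phylogenies: site matrix construction, distances,
# neighbor joining (via ape), outgroup rooting and bootstrap support.

#' Build the SNP-only site matrix for a set of haplotypes
#'
#' Keeps substitution (SNV) columns only. Positions overlapped by a
#' deletion or delins in any haplotype are eliminated (the "positions
#' containing gaps eliminated" rule), insertions contribute no reference
#' column, and the microsatellite window is excluded at calling time.
#' Columns that are monomorphic across the chosen taxa are dropped, so
#' every retained column is polymorphic.
#'
#' @param haplotypes A [call_panel()] tibble (`haplotype_id`, `variants`).
#' @param model A [gene_model()].
#' @param taxa Taxa to include (default all haplotype ids).
#' @return A `grf_snp_matrix`: character matrix (taxa x sites) with the
#'   genomic positions of the sites in `attr(, "positions")`.
#' @export
build_snp_matrix <- function(haplotypes, model, taxa = haplotypes$haplotype_id) {
  stopifnot(is.data.frame(haplotypes), inherits(model, "grf_gene_model"))
  rows <- match(taxa, haplotypes$haplotype_id)
  if (anyNA(rows)) abort("unknown taxa requested")
  vars <- haplotypes$variants[rows]

  snv_pos <- sort(unique(unlist(purrr::map(vars, function(v) {
    v$gstart[v$vclass == "SNV"]
  }))))
  gap_iv <- purrr::map_dfr(vars, function(v) {
    v[v$vclass %in% c("del", "delins"), c("gstart", "gend")]
  })
  if (nrow(gap_iv)) {
    in_gap <- vapply(snv_pos, function(p) {
      any(p >= gap_iv$gstart & p <= gap_iv$gend)
    }, TRUE)
    snv_pos <- snv_pos[!in_gap]
  }
  if (length(snv_pos) < 1L) {
    abort("degenerate matrix: fewer than 1 polymorphic substitution site")
  }
  m <- matrix("", nrow = length(taxa), ncol = length(snv_pos),
              dimnames = list(taxa, NULL))
  refs <- vapply(snv_pos, function(p) ref_base(model, p), "")
  for (i in seq_along(taxa)) {
    m[i, ] <- refs
    v <- vars[[i]]
    v <- v[v$vclass == "SNV" & v$gstart %in% snv_pos, , drop = FALSE]
    if (nrow(v)) m[i, match(v$gstart, snv_pos)] <- v$alt
  }
  poly <- apply(m, 2L, function(col) length(unique(col)) > 1L)
  if (!any(poly)) {
    abort("degenerate matrix: fewer than 1 polymorphic substitution site")
  }
  m <- m[, poly, drop = FALSE]
  structure(m, positions = snv_pos[poly], class = "grf_snp_matrix")
}

#' Pairwise distances from a site matrix
#'
#' p-distance (normalized mismatch fraction over columns) with optional
#' Jukes-Cantor correction. Any character is a state, so protein matrices
#' with `-` gap characters work unchanged (the gap acting as an extra
#' state).
#'
#' @param m A `grf_snp_matrix` or plain character matrix (taxa in rows).
#' @param correction `"p"` (default) or `"JC69"`
#'   (`-3/4 log(1 - 4p/3)`; undefined at p >= 0.75, which errors naming
#'   the offending pair).
#' @return A [stats::dist] with zero diagonal.
#' @export
distance_matrix <- function(m, correction = c("p", "JC69")) {
  correction <- match.arg(correction)
  m <- unclass(m)
  stopifnot(is.matrix(m), is.character(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- mean(m[i, ] != m[j, ])
      if (correction == "JC69") {
        if (p >= 0.75) {
          abort(sprintf("JC69 undefined for pair %s / %s (p = %.3f >= 0.75)",
                        rownames(m)[i], rownames(m)[j], p))
        }
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  as.dist(d)
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining (Saitou-Nei, as implemented in ape) on a
#' distance matrix; exact on additive distances.
#'
#' @param d A [stats::dist] or symmetric matrix, >= 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.dist(d)
  if (attr(d, "Size") < 3L) abort("neighbor joining needs at least 3 taxa")
  ape::nj(d)
}

#' Root a tree on an outgroup taxon
#'
#' Places the root on the outgroup's pendant edge.
#'
#' @param tree A `phylo` tree.
#' @param outgroup A tip label present in the tree.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label) {
    abort(sprintf("unknown taxon '%s'", outgroup))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples matrix columns with replacement, rebuilds the NJ tree per
#' replicate and maps internal-edge bipartition frequencies (percent of
#' replicates) onto the full-data tree as node labels. Seeded and
#' reproducible.
#'
#' @param m A `grf_snp_matrix` or character matrix.
#' @param reps Number of bootstrap replicates (>= 1; 500 in the study).
#' @param seed Integer seed for the resampling.
#' @param correction Distance correction passed to [distance_matrix()].
#' @return The full-data NJ `phylo` tree with `node.label` holding percent
#'   support (the root node label is empty).
#' @export
bootstrap_support <- function(m, reps = 500L, seed = 1L,
                              correction = c("p", "JC69")) {
  correction <- match.arg(correction)
  stopifnot(.is_count(reps), reps >= 1L)
  mm <- unclass(m)
  fun <- function(x) nj_tree(distance_matrix(x, correction))
  phy <- fun(mm)
  counts <- .with_seed(seed, {
    ape::boot.phylo(phy, mm, fun, B = reps, quiet = TRUE, rooted = FALSE)
  })
  support <- round(100 * counts / reps)
  support[1L] <- NA  # the root "bipartition" is trivial
  phy$node.label <- ifelse(is.na(support), "", as.character(support))
  phy
}

#' Project haplotype proteins onto reference residue columns
#'
#' Builds a taxa x residue character matrix for protein trees: each protein
#' is laid against the reference protein, with `-` filling deleted residue
#' positions. Gap columns are retained as characters (the gap counting as
#' an extra state in [distance_matrix()]), so length polymorphism in the
#' polyglutamine tract contributes to protein distances. Proteins longer
#' than the reference (insertions) are not supported.
#'
#' @param proteins Named character vector of proteins (e.g. from
#'   [group_isoforms()]: `setNames(groups$protein, groups$letter)`).
#' @param ref_protein The reference protein the coordinates refer to.
#' @return Character matrix, one row per protein.
#' @export
build_protein_matrix <- function(proteins, ref_protein) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  nr <- nchar(ref_protein)
  rows <- purrr::map(proteins, function(p) {
    if (nchar(p) > nr) abort("protein longer than reference: insertions unsupported")
    a <- strsplit(p, "", fixed = TRUE)[[1]]
    r <- strsplit(ref_protein, "", fixed = TRUE)[[1]]
    if (nchar(p) == nr) return(a)
    nmin <- length(a)
    pre <- 0L
    while (pre < nmin && a[pre + 1L] == r[pre + 1L]) pre <- pre + 1L
    suf <- 0L
    while (suf < nmin - pre && a[length(a) - suf] == r[length(r) - suf]) suf <- suf + 1L
    c(a[seq_len(pre)], rep("-", nr - length(a)),
      a[seq(pre + 1L, length.out = length(a) - pre)])
  })
  do.call(rbind, rows)
}
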