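# Independent oracles: implemented from first principles, sharing no code
# with the package internals they check.

# Brute-force HGVS coding address of a genomic position: enumerate the
# transcript by walking exon positions in coding order and count.
oracle_coding_address <- function(model, g) {
  off <- model$offset
  L <- nchar(model$sequence)
  axis_g <- if (model$strand == "+") off:(off + L - 1L) else (off + L - 1L):off
  ex_pos <- unlist(lapply(seq_len(nrow(model$exons)), function(k) {
    model$exons[k, 1L]:model$exons[k, 2L]
  }))
  ex_order <- if (model$strand == "+") sort(ex_pos) else sort(ex_pos, decreasing = TRUE)
  cds_first <- if (model$strand == "+") model$cds_start else model$cds_end
  cds_last <- if (model$strand == "+") model$cds_end else model$cds_start
  S <- match(cds_first, ex_order)
  E <- match(cds_last, ex_order)
  T_len <- length(ex_order)
  addr <- function(t) {
    if (t < S) paste0("-", S - t)
    else if (t > E) paste0("*", t - E)
    else as.character(t - S + 1L)
  }
  t_g <- match(g, ex_order)
  if (!is.na(t_g)) return(addr(t_g))
  i <- match(g, axis_g)
  exon_axis <- sort(match(ex_order, axis_g))
  if (i < min(exon_axis)) return(paste0("-", (S - 1L) + (min(exon_axis) - i)))
  if (i > max(exon_axis)) return(paste0("*", (T_len - E) + (i - max(exon_axis))))
  prev_e <- max(exon_axis[exon_axis < i])
  next_s <- min(exon_axis[exon_axis > i])
  d5 <- i - prev_e
  d3 <- next_s - i
  if (d5 <= d3) {
    t <- match(axis_g[prev_e], ex_order)
    paste0(addr(t), "+", d5)
  } else {
    t <- match(axis_g[next_s], ex_order)
    paste0(addr(t), "-", d3)
  }
}

# Quadratic affine-gap Needleman-Wunsch score (gap of length L costs
# open + L * extend), Gotoh three-matrix recursion.
oracle_nw_score <- function(a, b, match = 1, mismatch = -2, open = 6, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)  # ends in match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (horizontal)
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) X[i, 1L] <- -open - (i - 1L) * extend
  for (j in 2L:(m + 1L)) Y[1L, j] <- -open - (j - 1L) * extend
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (av[i - 1L] == bv[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - open - extend, X[i - 1L, j] - extend)
      Y[i, j] <- max(M[i, j - 1L] - open - extend, Y[i, j - 1L] - extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Exact two-sided Fisher p by full enumeration over tables with the
# observed margins, probabilities from choose().
oracle_fisher_p <- function(tab) {
  a <- tab[1L, 1L]
  r1 <- sum(tab[1L, ])
  r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L])
  N <- r1 + r2
  as <- max(0L, c1 - r2):min(r1, c1)
  probs <- choose(r1, as) * choose(r2, c1 - as) / choose(N, c1)
  p_obs <- probs[match(a, as)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Plant one random canonical (3'-shifted, coding strand) variant on a model.
# The coding-strand sequence, coordinate mapping and expected HGVS names are
# all derived here from first principles (oracle_coding_address), sharing
# nothing with the package's caller/namer.
plant_random_variant <- function(model) {
  L <- nchar(model$sequence)
  off <- model$offset
  plus <- model$sequence
  sq <- if (model$strand == "+") plus else grfhap::revcomp(plus)
  g_of_axis <- function(j) if (model$strand == "+") off + j - 1L else off + (L - j)
  base_at <- function(j) substr(sq, j, j)
  ca <- function(j) oracle_coding_address(model, g_of_axis(j))
  ctg <- model$contig
  repeat {
    type <- sample(c("SNV", "del", "ins"), 1L)
    if (type == "SNV") {
      j <- sample(3:(L - 3L), 1L)
      ref <- base_at(j)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      g <- g_of_axis(j)
      row <- tibble::tibble(
        gstart = g, gend = g,
        ref = if (model$strand == "+") ref else grfhap::revcomp(ref),
        alt = if (model$strand == "+") alt else grfhap::revcomp(alt)
      )
      name_g <- sprintf("%s:g.%d%s>%s", ctg, g, row$ref, row$alt)
      name_c <- sprintf("c.%s%s>%s", ca(j), ref, alt)
      break
    } else if (type == "del") {
      len <- sample(1:6, 1L)
      j1 <- sample(3:(L - len - 3L), 1L)
      j2 <- j1 + len - 1L
      if (base_at(j2 + 1L) == base_at(j1)) next  # not 3'-most, resample
      gs <- sort(c(g_of_axis(j1), g_of_axis(j2)))
      ref <- substr(plus, gs[1L] - off + 1L, gs[2L] - off + 1L)
      row <- tibble::tibble(gstart = gs[1L], gend = gs[2L], ref = ref, alt = "")
      name_g <- if (gs[1L] == gs[2L]) sprintf("%s:g.%ddel", ctg, gs[1L])
                else sprintf("%s:g.%d_%ddel", ctg, gs[1L], gs[2L])
      name_c <- if (j1 == j2) sprintf("c.%sdel", ca(j1))
                else sprintf("c.%s_%sdel", ca(j1), ca(j2))
      break
    } else {
      len <- sample(1:5, 1L)
      j <- sample(3:(L - 3L), 1L)
      x <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
      if (substr(x, 1L, 1L) == base_at(j + 1L)) next  # shiftable, resample
      gs <- sort(c(g_of_axis(j), g_of_axis(j + 1L)))
      row <- tibble::tibble(gstart = gs[1L], gend = gs[2L], ref = "",
                            alt = if (model$strand == "+") x else grfhap::revcomp(x))
      name_g <- sprintf("%s:g.%d_%dins%s", ctg, gs[1L], gs[2L], row$alt)
      name_c <- sprintf("c.%s_%sins%s", ca(j), ca(j + 1L), x)
      break
    }
  }
  list(sequence = apply_variants(model, row), name_g = name_g, name_c = name_c,
       vclass = type)
}
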