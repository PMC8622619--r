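test_that("the SNP matrix keeps substitution columns and eliminates indel columns", {
  m <- fixture_model()
  # two haplotypes differing by one SNV and one indel -> exactly 1 column
  s1 <- apply_variants(m, c("c.495G>T", "c.126_134del"))
  calls <- call_panel(m, c(ref = m$sequence, mut = s1))
  sm <- build_snp_matrix(calls, m)
  expect_identical(ncol(sm), 1L)
  expect_identical(attr(sm, "positions"), 687050412L)
  expect_error(build_snp_matrix(calls, m, taxa = "nope"), "unknown taxa")
  # identical haplotypes alone have no polymorphic site
  same <- call_panel(m, c(a = m$sequence, b = m$sequence))
  expect_error(build_snp_matrix(same, m), "degenerate")
})

test_that("gap-column elimination groups the deletion haplotype with the reference", {
  sm <- build_snp_matrix(fixture_calls(), fixture_model())
  d <- as.matrix(distance_matrix(sm))
  calls <- fixture_calls()
  hap_of <- function(al) {
    calls$haplotype_id[vapply(seq_len(nrow(calls)),
                              function(i) fixture_allele_of(calls[i, ]) == al, TRUE)]
  }
  # a.1-like and d.1-like differ only by the deletion, eliminated as a gap
  expect_identical(d[hap_of("a1"), hap_of("d1")], 0)
  # adding an indel-only haplotype never changes existing pairwise distances
  sub <- build_snp_matrix(calls, fixture_model(),
                          taxa = setdiff(calls$haplotype_id, hap_of("d1")))
  dsub <- as.matrix(distance_matrix(sub))
  common <- rownames(dsub)
  expect_equal(d[common, common], dsub)
})

test_that("distances match a brute-force mismatch count and ape::dist.dna", {
  set.seed(707)
  for (i in 1:5) {
    base <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
    mm <- t(vapply(1:6, function(k) {
      x <- base
      idx <- sample(40, sample(3:12, 1))  # a few substitutions per taxon
      x[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
      x
    }, character(40)))
    rownames(mm) <- paste0("t", 1:6)
    d <- as.matrix(distance_matrix(mm))
    for (a in 1:5) for (b in (a + 1):6) {
      expect_identical(d[a, b], sum(mm[a, ] != mm[b, ]) / ncol(mm))
    }
    ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(mm), model = "raw"))
    expect_equal(d, ref, ignore_attr = TRUE)
    refjc <- as.matrix(ape::dist.dna(ape::as.DNAbin(mm), model = "JC69"))
    expect_equal(as.matrix(distance_matrix(mm, "JC69")), refjc,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # JC69 undefined at p >= 0.75, error names the pair
  bad <- rbind(x = rep("A", 8), y = rep("C", 8))
  expect_error(distance_matrix(bad, "JC69"), "x / y")
})

test_that("neighbor joining is exact on additive distances from random trees", {
  set.seed(808)
  for (i in 1:20) {
    nt <- sample(5:8, 1)
    tr <- ape::rtree(nt, br = function(n) runif(n, 0.05, 1))
    d <- cophenetic(tr)
    est <- nj_tree(as.dist(d))
    expect_identical(as.numeric(ape::dist.topo(ape::unroot(tr), est)), 0)
    expect_equal(cophenetic(est)[rownames(d), colnames(d)], d, tolerance = 1e-8)
  }
  expect_error(nj_tree(dist(matrix(1:4, 2))), "at least 3")
})

test_that("NJ topology is invariant to taxon order", {
  set.seed(809)
  tr <- ape::rtree(7)
  d <- cophenetic(tr)
  perm <- sample(rownames(d))
  t1 <- nj_tree(as.dist(d))
  t2 <- nj_tree(as.dist(d[perm, perm]))
  expect_identical(as.numeric(ape::dist.topo(t1, t2)), 0)
  # tree length is invariant under relabeling
  expect_equal(sum(t1$edge.length), sum(t2$edge.length))
})

test_that("outgroup rooting places the root on the outgroup's pendant edge", {
  set.seed(810)
  tr <- ape::rtree(6)
  un <- ape::unroot(tr)
  rt <- root_with_outgroup(un, "t3")
  expect_true(ape::is.rooted(rt))
  # the outgroup descends directly from the root
  root_children <- rt$edge[rt$edge[, 1L] == ape::Ntip(rt) + 1L, 2L]
  expect_true(match("t3", rt$tip.label) %in% root_children)
  expect_error(root_with_outgroup(un, "t99"), "unknown taxon")
  # unroot -> reroot round trip preserves the topology
  expect_identical(as.numeric(ape::dist.topo(ape::unroot(rt), un)), 0)
})

test_that("bootstrap supports are seeded, bounded and resolve clear clades", {
  # 8 taxa in two clades, 10 diagnostic sites each + 3 noise sites
  taxa <- paste0("t", 1:8)
  mm <- matrix("A", 8, 23, dimnames = list(taxa, NULL))
  mm[1:4, 1:10] <- "G"
  mm[5:8, 11:20] <- "T"
  set.seed(1); mm[, 21:23] <- sample(c("A", "C"), 24, replace = TRUE)
  b1 <- bootstrap_support(mm, reps = 200L, seed = 99L)
  b2 <- bootstrap_support(mm, reps = 200L, seed = 99L)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  sup <- suppressWarnings(as.numeric(b1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_gte(max(sup), 90)  # the two-clade split is near-certain
  # reps = 1: supports only 0 or 100
  s1 <- bootstrap_support(mm, reps = 1L, seed = 3L)
  v <- suppressWarnings(as.numeric(s1$node.label))
  expect_true(all(v[!is.na(v)] %in% c(0, 100)))
})

test_that("protein matrices retain gaps as characters at the 3'-most placement", {
  m <- fixture_model()
  g <- group_isoforms(fixture_calls(), m)
  pm <- build_protein_matrix(setNames(g$protein, g$letter), translate_cds(m))
  expect_identical(nrow(pm), 4L)
  expect_identical(ncol(pm), nchar(translate_cds(m)))
  expect_identical(unname(pm["D", 42:44]), rep("-", 3))  # Gln42_Gln44del
  expect_identical(unname(pm["B", 165]), "H")
  d <- as.matrix(distance_matrix(pm))
  expect_identical(d["A", "D"], 3 / ncol(pm))  # gap = 21st state
  tr <- nj_tree(distance_matrix(pm))
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
})
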