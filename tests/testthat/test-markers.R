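test_that("the Q42 deletion marker: 344 bp wild type, 335 bp after the 9-nt deletion", {
  ms <- grf_marker_set()
  wt <- insilico_pcr(fixture_seq_for("a1"), ms$q42)
  del <- insilico_pcr(fixture_seq_for("d1"), ms$q42)
  expect_identical(wt$length, 344L)
  expect_identical(del$length, 335L)
})

test_that("the Q165 CAPS marker distinguishes c.495 alleles", {
  ms <- grf_marker_set()
  amp_g <- insilico_pcr(fixture_seq_for("a1"), ms$q165)
  amp_t <- insilico_pcr(fixture_seq_for("b1"), ms$q165)
  expect_identical(amp_g$length, 454L)
  expect_identical(amp_t$length, 454L)
  # G allele: no SfaN I site, amplicon intact
  expect_identical(caps_digest(amp_g$sequence, ms$sfani), 454L)
  # T allele: one site; top-strand cut 201 nt from the 5' end, larger
  # fragment 253; bottom-strand convention shifts by the 4-nt stagger
  expect_identical(caps_digest(amp_t$sequence, ms$sfani), c(201L, 253L))
  expect_identical(caps_digest(amp_t$sequence, ms$sfani, "bottom"), c(205L, 249L))
})

test_that("a single-base substitution toggles the fragment count (CAPS principle)", {
  ms <- grf_marker_set()
  amp_g <- insilico_pcr(fixture_seq_for("a1"), ms$q165)$sequence
  amp_t <- insilico_pcr(fixture_seq_for("b1"), ms$q165)$sequence
  expect_identical(length(caps_digest(amp_g, ms$sfani)), 1L)
  expect_identical(length(caps_digest(amp_t, ms$sfani)), 2L)
  # the two amplicons differ by exactly the diagnostic base
  expect_identical(sum(strsplit(amp_g, "")[[1]] != strsplit(amp_t, "")[[1]]), 1L)
})

test_that("digestion conserves total length for random enzymes and amplicons", {
  set.seed(606)
  for (i in 1:25) {
    amp <- paste(sample(c("A", "C", "G", "T"), sample(80:400, 1), replace = TRUE),
                 collapse = "")
    rec <- paste(sample(c("A", "C", "G", "T"), sample(4:6, 1), replace = TRUE),
                 collapse = "")
    enz <- restriction_enzyme("rnd", rec, sample(0:8, 1), sample(0:8, 1))
    for (conv in c("top", "bottom")) {
      frags <- suppressWarnings(caps_digest(amp, enz, conv))
      expect_identical(sum(frags), nchar(amp))
      expect_true(all(frags > 0L))
    }
  }
})

test_that("PCR finds products on either strand with identical lengths", {
  set.seed(607)
  tpl <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  f <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  r <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  tpl <- paste0(substr(tpl, 1, 100), f, substr(tpl, 121, 400), revcomp(r),
                substr(tpl, 421, 600))
  pp <- primer_pair("t", f, r, max_product = 500L)
  fwd <- insilico_pcr(tpl, pp)
  rev <- insilico_pcr(revcomp(tpl), pp)
  expect_identical(fwd$length, 320L)  # planted distance, footprints inclusive
  expect_identical(sort(rev$length), sort(fwd$length))
  expect_identical(rev$strand, "-")
  # a template lacking a primer site gives no product, not an error
  expect_identical(nrow(insilico_pcr(substr(tpl, 150, 400), pp)), 0L)
})

test_that("deleting k bases strictly between the primer footprints shrinks the product by k", {
  m <- fixture_model()
  ms <- grf_marker_set()
  base <- insilico_pcr(m$sequence, ms$q42)$length
  for (k in c(1L, 4L, 9L, 17L)) {
    g1 <- coding_to_genomic(m, "150")
    s <- apply_variants(m, tibble::tibble(
      gstart = g1, gend = g1 + k - 1L,
      ref = substr(m$sequence, g1 - m$offset + 1L, g1 + k - 1L - m$offset + 1L),
      alt = ""
    ))
    expect_identical(insilico_pcr(s, ms$q42)$length, base - k)
  }
})

test_that("mismatch tolerance requires an exact 3'-terminal 5-mer", {
  set.seed(608)
  tpl <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  f <- substr(tpl, 51, 72)
  r <- revcomp(substr(tpl, 181, 202))
  pp <- primer_pair("t", f, r, 400L)
  expect_identical(insilico_pcr(tpl, pp)$length, 152L)
  # one internal mismatch in the forward primer: lost at 0, found at 1
  fv <- strsplit(f, "")[[1]]
  fv[8] <- setdiff(c("A", "C", "G", "T"), fv[8])[1]
  pp1 <- primer_pair("t", paste(fv, collapse = ""), r, 400L)
  expect_identical(nrow(insilico_pcr(tpl, pp1)), 0L)
  expect_identical(insilico_pcr(tpl, pp1, max_mismatch = 1L)$length, 152L)
  # a mismatch in the 3'-terminal 5-mer is never tolerated
  fv2 <- strsplit(f, "")[[1]]
  fv2[21] <- setdiff(c("A", "C", "G", "T"), fv2[21])[1]
  pp2 <- primer_pair("t", paste(fv2, collapse = ""), r, 400L)
  expect_identical(nrow(insilico_pcr(tpl, pp2, max_mismatch = 2L)), 0L)
})

test_that("SSR products land in disjoint homoeolog bins; gaps stay unassigned", {
  ms <- grf_marker_set()
  g <- ssr_genotype(c(240, 215, 225), ms$bins)
  expect_identical(g$locus, c("2A", "2D", NA_character_))
  expect_error(ssr_bins(a = c(1, 10), b = c(10, 20)), "overlap")
  # planted repeat counts shift the product by 2 nt per repeat unit
  for (al in c("a1", "a17", "c1")) {
    n_rep <- grf_allele_catalog()$ssr_n[grf_allele_catalog()$allele == al]
    got <- insilico_pcr(fixture_seq_for(al), ms$ssr)$length
    expect_identical(got, 208L + 2L * n_rep)
    expect_identical(ssr_genotype(got, ms$bins)$locus, "2A")
  }
})

test_that("marker definitions validate their invariants", {
  expect_error(primer_pair("x", "ACGTACGT", "ACGTACGTACGTACGTACGT"), "15 nt")
  expect_error(primer_pair("x", strrep("AC", 10), strrep("GT", 10),
                           max_product = 30L), "max_product")
  expect_error(restriction_enzyme("x", "GCATC", -1L, 9L))
})

test_that("genotype_markers reads all three assays across the panel truth", {
  pan <- fixture_panel()
  truth <- pan$truth
  picks <- vapply(c("a1", "b1", "d1", "a17"), function(al) {
    which(truth$allele == al)[1]
  }, 1L)
  gm <- genotype_markers(pan$sequences[picks])
  expect_identical(gm$q42_bp, c(344L, 344L, 335L, 344L))
  expect_identical(gm$c495_allele, c("G", "T", "G", "G"))
  expect_identical(gm$ssr_bp, c(260L, 268L, 260L, 282L))
  expect_identical(unique(gm$ssr_locus), "2A")
})
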