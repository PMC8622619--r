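test_that("alignment of identical sequences has no gaps or mismatches", {
  m <- fixture_model()
  a <- align_to_reference(m$sequence, m$sequence)
  expect_identical(a$ref, a$query)
  expect_false(grepl("-", a$ref, fixed = TRUE))
  expect_identical(nrow(call_variants(m, a)), 0L)
  expect_error(align_to_reference("ACGT", "ACXT"), "outside")
})

test_that("the 9-nt deletion allele aligns with a single 9-nt gap", {
  m <- fixture_model()
  s <- apply_variants(m, "c.126_134del")
  a <- align_to_reference(m$sequence, s)
  gaps <- gregexpr("-+", a$query)[[1]]
  expect_identical(length(gaps), 1L)
  expect_identical(attr(gaps, "match.length"), 9L)
  expect_false(grepl("-", a$ref, fixed = TRUE))
})

test_that("alignment scores equal the quadratic dynamic-programming oracle", {
  set.seed(404)
  for (i in 1:6) {
    a <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    bv <- strsplit(a, "")[[1]]
    for (k in 1:5) { # 5 random edits: substitutions and small indels
      op <- sample(3, 1)
      pos <- sample(20:180, 1)
      if (op == 1) bv[pos] <- sample(c("A", "C", "G", "T"), 1)
      else if (op == 2) bv <- bv[-(pos:(pos + sample(3, 1)))]
      else bv <- append(bv, sample(c("A", "C", "G", "T"), sample(3, 1),
                                   replace = TRUE), after = pos)
    }
    b <- paste(bv, collapse = "")
    got <- align_to_reference(a, b)$score
    expect_equal(got, oracle_nw_score(a, b))
  }
})

test_that("replayed alleles yield exactly the printed variant calls", {
  m <- fixture_model()
  vb <- call_variants(m, query = fixture_seq_for("b1"))
  expect_setequal(vb$name_c, c("c.-561G>C", "c.495G>T"))  # promoter SNP + c.495
  expect_identical(vb$name_c[vb$gstart == 687050412L], "c.495G>T")
  # the two adjacent urartu substitutions separated by one matching base
  # stay separate SNVs, never merged into a delins
  vc <- call_variants(m, query = fixture_seq_for("c1"))
  expect_true(all(c("c.528G>C", "c.530C>G") %in% vc$name_c))
  expect_false(any(vc$vclass == "delins"))
})

test_that("truly adjacent mismatching columns merge into a delins", {
  m <- fixture_model()
  g <- coding_to_genomic(m, "600")
  i <- g - m$offset + 1L
  ref2 <- substr(m$sequence, i, i + 1L)
  alt2 <- chartr("ACGT", "CATG", ref2)  # change both bases
  s <- apply_variants(m, tibble::tibble(gstart = g, gend = g + 1L,
                                        ref = ref2, alt = alt2))
  v <- call_variants(m, query = s)
  expect_identical(v$vclass, "delins")
  expect_identical(v$name_c, sprintf("c.600_601delins%s", alt2))
})

test_that("apply -> call round trip recovers planted variants with exact names", {
  set.seed(505)
  n_ok <- 0L
  for (i in 1:20) {
    m <- random_gene_model()
    for (k in 1:10) {
      pl <- plant_random_variant(m)
      v <- call_variants(m, query = pl$sequence)
      expect_identical(nrow(v), 1L)
      expect_identical(v$name_g, pl$name_g)
      expect_identical(v$name_c, pl$name_c)
      n_ok <- n_ok + 1L
    }
  }
  expect_identical(n_ok, 200L)
})

test_that("microsatellite measurement counts units, length and interruptions", {
  m <- fixture_model()
  # reference tract: (AG)26, pure
  expect_identical(
    measure_ssr(m, m$sequence),
    tibble::tibble(repeat_count = 26L, tract_length = 52L,
                   interrupted = FALSE, found = TRUE)
  )
  # (AG)11 allele
  cat11 <- dplyr::filter(grf_allele_catalog(), allele == "c1")
  s11 <- fixture_seq_for("c1")
  expect_identical(measure_ssr(m, s11)$repeat_count, 11L)
  expect_identical(measure_ssr(m, s11)$tract_length, 22L)
  # (AG)28 with one A lost: 55 nt, interrupted; (AG)31 - A: 61 nt
  r28 <- measure_ssr(m, fixture_seq_for("a2"))
  expect_identical(r28$tract_length, 55L)
  expect_true(r28$interrupted)
  expect_identical(measure_ssr(m, fixture_seq_for("a3"))$tract_length, 61L)
  # window deleted from the query -> zero-length tract with flag
  w <- m$ssr_locus$window
  del <- tibble::tibble(gstart = w[1L] - 6L, gend = w[2L] + 6L,
                        ref = substr(m$sequence, w[1L] - 6L - m$offset + 1L,
                                     w[2L] + 6L - m$offset + 1L),
                        alt = "")
  gone <- measure_ssr(m, apply_variants(m, del))
  expect_identical(gone$tract_length, 0L)
  expect_false(gone$found)
})

test_that("round trip through the generator: planted SSR lengths are re-measured", {
  m <- fixture_model()
  pan <- fixture_panel()
  calls <- fixture_calls()
  truth <- pan$truth
  for (i in seq_len(nrow(calls))) {
    acc <- calls$accessions[[i]][1]
    expect_identical(calls$ssr_repeat_count[i],
                     truth$ssr_repeat_count[truth$accession == acc][1])
    expect_identical(calls$ssr_tract_length[i],
                     truth$ssr_tract_length[truth$accession == acc][1])
  }
})

test_that("haplotype collapsing groups identical sequences, order-invariantly", {
  seqs <- c(x1 = "ACGT", x2 = "ACGT", x3 = "ACGT", y1 = "ACGA", y2 = "ACGA",
            z1 = "AAAA")
  h <- collapse_haplotypes(seqs)
  expect_identical(h$n, c(3L, 2L, 1L))
  expect_identical(h$haplotype_id, c("H01", "H02", "H03"))
  expect_identical(h$accessions[[1L]], c("x1", "x2", "x3"))
  set.seed(1)
  h2 <- collapse_haplotypes(seqs[sample(length(seqs))])
  expect_identical(h, h2)
  # member counts sum to the panel size
  expect_identical(sum(fixture_calls()$n), 199L)
})

test_that("the VCF writer left-aligns and anchors indels", {
  m <- fixture_model()
  v <- call_variants(m, query = apply_variants(m, "c.126_134del"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(m, v, path)
  lines <- readLines(path)
  expect_identical(lines[1L], "##fileformat=VCFv4.2")
  rec <- strsplit(grep("^chr2A", lines, value = TRUE), "\t")[[1]]
  pos <- as.integer(rec[2L])
  # VCF is left-aligned: the deletion slides to the 5' end of the CAG run
  # and gains a one-base anchor; HGVS (3'-shifted) sits at c.126_134
  expect_lt(pos, coding_to_genomic(m, "126"))
  ref_field <- rec[4L]
  alt_field <- rec[5L]
  expect_identical(nchar(ref_field) - nchar(alt_field), 9L)
  expect_identical(substr(ref_field, 1L, 1L), alt_field)
  slice <- substr(m$sequence, pos - m$offset + 1L,
                  pos - m$offset + nchar(ref_field))
  expect_identical(slice, ref_field)
  expect_identical(rec[3L], "c.126_134del")
})
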