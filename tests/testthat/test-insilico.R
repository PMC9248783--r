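test_that("degenerate expansion counts equal brute-force enumeration", {
  expect_equal(expand_degenerate("ACGT"), 1)
  # per-position degeneracies of the two assay primers: V,Y,Y,N,N,Y and D,H,D,N,Y
  expect_equal(expand_degenerate("EW_COI_F2"), 3 * 2 * 2 * 4 * 4 * 2)
  expect_equal(expand_degenerate("EW_COI_R1"), 3 * 3 * 3 * 4 * 2)
  for (p in c("EW_COI_F2", "EW_COI_R1", "EW_COI_F3")) {
    vars <- enumerate_variants(p)
    expect_equal(length(vars), expand_degenerate(p))
    expect_equal(anyDuplicated(vars), 0L)
    expect_false(is.unsorted(vars))  # lexicographic
  }
  expect_error(expand_degenerate("ACGU"), "position 4")
  expect_error(enumerate_variants("NNNNNNNNNN", max_variants = 100),
               "max_variants")
})

test_that("binding-site search honors strands, anchors and mismatch caps", {
  set.seed(1)
  primer <- "EW_COI_F2"
  inst <- enumerate_variants(primer)[[17L]]
  left <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  template <- paste0(left, inst, right)
  hits <- find_binding_sites(template, primer)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 10L)
  expect_equal(plus$end, 10L + nchar(inst))
  expect_equal(plus$mismatches, 0L)

  # reverse-complemented instance is found on the minus strand
  template_rc <- paste0(left, revcomp(inst), right)
  hits_rc <- find_binding_sites(template_rc, primer)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, 10L)

  # one mismatch placed in the 3' anchor kills the hit even at max_mismatch 2
  broken <- inst
  last <- nchar(inst)
  substr(broken, last, last) <- setdiff(c("A", "C", "G", "T"),
                                        substr(inst, last, last))[[1L]]
  t2 <- paste0(left, broken, right)
  expect_equal(nrow(find_binding_sites(t2, primer, max_mismatch = 2)), 0L)
  # the same substitution outside the anchor is tolerated
  broken2 <- inst
  substr(broken2, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                   substr(inst, 5, 5))[[1L]]
  t3 <- paste0(left, broken2, right)
  expect_equal(nrow(find_binding_sites(t3, primer, max_mismatch = 0)), 0L)
  h3 <- find_binding_sites(t3, primer, max_mismatch = 1)
  expect_equal(h3$mismatches, 1L)

  # template shorter than the primer: empty result, not an error
  expect_equal(nrow(find_binding_sites("ACGT", primer)), 0L)
})

test_that("template N is conservative by default, intersecting when permissive", {
  inst <- enumerate_variants("EW_COI_F2")[[1L]]
  with_n <- inst
  substr(with_n, 5, 5) <- "N"
  expect_equal(nrow(find_binding_sites(with_n, "EW_COI_F2")), 0L)
  expect_equal(nrow(find_binding_sites(with_n, "EW_COI_F2",
                                       permissive_n = TRUE)), 1L)
  expect_error(find_binding_sites("ACGX", "EW_COI_F2"), "position 4")
})

test_that("amplicon prediction pairs sites and counts primer footprints", {
  set.seed(2)
  fwd <- "EW_COI_F2"  # 23 bases
  rev <- "EW_COI_R1"  # 20 bases
  fi <- enumerate_variants(fwd)[[1L]]
  ri <- enumerate_variants(rev)[[1L]]
  core <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
  template <- paste0(fi, core, revcomp(ri))
  amps <- predict_amplicons(c(t1 = template), fwd, rev)
  expect_equal(nrow(amps), 1L)
  expect_equal(amps$length, 23L + 10L + 20L)
  expect_equal(amps$core, core)
  expect_equal(amps$sequence, template)
  expect_equal(amps$gc_fraction,
               mean(strsplit(template, "")[[1]] %in% c("G", "C")))

  # no reverse site downstream -> empty
  expect_equal(nrow(predict_amplicons(c(t1 = paste0(fi, core)), fwd, rev)), 0L)
})

test_that("predicted product lengths satisfy offset additivity across the panel", {
  ref <- simulate_coi_reference(seed = 4)
  fwds <- paste0("EW_COI_F", 1:3)
  revs <- paste0("EW_COI_R", 1:3)
  L <- matrix(NA_real_, 3, 3, dimnames = list(fwds, revs))
  for (f in fwds) for (r in revs) {
    a <- predict_amplicons(ref, f, r)
    expect_equal(nrow(a), 1L)
    L[f, r] <- a$length
  }
  # row and column differences must be constant (sites are fixed loci)
  for (j in 2:3) expect_equal(unname(L[, j] - L[, 1L]),
                              rep(L[1L, j] - L[1L, 1L], 3))
  for (i in 2:3) expect_equal(unname(L[i, ] - L[1L, ]),
                              rep(L[i, 1L] - L[1L, 1L], 3))
})

test_that("strand symmetry: the reverse-complement template with swapped roles", {
  ref <- simulate_coi_reference(seed = 8)
  fwd <- "EW_COI_F2"; rev <- "EW_COI_R1"
  a1 <- predict_amplicons(ref, fwd, rev)
  flipped <- tibble::tibble(label = ref$label, sequence = revcomp(ref$sequence))
  a2 <- predict_amplicons(flipped, rev, fwd)
  expect_equal(sort(a2$length), sort(a1$length))
})

test_that("multiplex prediction surfaces per-pair products and violations", {
  set.seed(3)
  p16 <- list(p16S = c("16S-Ac-F1", "WORM-16S-R1"),
              pCOI = c("COI-Al-F2", "COI-Al-R2"))
  mk <- function(f, r, core_n) paste0(get_primer(f),
                                      paste(sample(c("A","C","G","T"), core_n,
                                                   TRUE), collapse = ""),
                                      revcomp(get_primer(r)))
  cal <- mk("16S-Ac-F1", "WORM-16S-R1", 76)   # 116 bp product
  lon <- mk("COI-Al-F2", "COI-Al-R2", 173)    # 213 bp product
  both <- paste0(cal, "ACGTACGT", lon)
  none <- paste(sample(c("A","C","G","T"), 150, TRUE), collapse = "")
  m <- multiplex_predict(c(cal = cal, lon = lon, both = both, none = none),
                         p16)
  expect_equal(m$lengths_txt[m$template_id == "cal" & m$pair == "p16S"], "116")
  expect_equal(m$lengths_txt[m$template_id == "cal" & m$pair == "pCOI"], "")
  expect_equal(m$lengths_txt[m$template_id == "lon" & m$pair == "pCOI"], "213")
  expect_equal(m$n_products[m$template_id == "none"], c(0L, 0L))
  # a template carrying both pairs' sites reports both products, not hidden
  expect_equal(m$lengths_txt[m$template_id == "both" & m$pair == "p16S"], "116")
  expect_equal(m$lengths_txt[m$template_id == "both" & m$pair == "pCOI"], "213")
  expect_error(multiplex_predict(c(a = cal, a = lon), p16), "duplicate")
})

test_that("zero-mismatch binding agrees with Biostrings IUPAC matching", {
  set.seed(6)
  template <- simulate_coi_reference(seed = 6)$sequence
  for (p in c("EW_COI_F1", "EW_COI_R2")) {
    mine <- find_binding_sites(template, p)
    mine_plus <- mine[mine$strand == "+", ]
    ref_hits <- Biostrings::matchPattern(
      Biostrings::DNAString(get_primer(p)),
      Biostrings::DNAString(template),
      fixed = FALSE)
    expect_equal(mine_plus$start, BiocGenerics::start(ref_hits) - 1L)
  }
})
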