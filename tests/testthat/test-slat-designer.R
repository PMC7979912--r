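test_that("domain layouts satisfy the half-turn window-sum rule", {
  l6 <- domainLayout(6, 10.5)
  expect_equal(length(l6@lengths), 12L)
  expect_equal(sum(l6@lengths), 63L)
  for (i in 1:9) expect_equal(sum(l6@lengths[i:(i + 3)]), 21L)
  l8 <- domainLayout(8, 11.0)
  expect_equal(l8@lengths, rep(c(5L, 6L), 8))
  expect_equal(sum(l8@lengths), 88L)
  for (i in 1:13) expect_equal(sum(l8@lengths[i:(i + 3)]), 22L)
  expect_error(domainLayout(6, 10.3), "unattainable")
  # phase rotates the pattern but preserves window sums
  lp <- domainLayout(6, 10.5, phase = 1)
  for (i in 1:9) expect_equal(sum(lp@lengths[i:(i + 3)]), 21L)
  expect_false(identical(lp@lengths, l6@lengths))
})

test_that("blueprint crossing maps are bijective with the right slat counts", {
  for (cfg in list(list(n = 6, mode = "full", u = 12),
                   list(n = 8, mode = "n_pairs", u = 8),
                   list(n = 8, mode = "half_n_pairs", u = 4))) {
    bp <- buildBlueprint(domainLayout(cfg$n, 10.5), cfg$mode)
    expect_equal(bp@period, cfg$u)
    expect_equal(length(nucYSlats(bp)), 2L * cfg$n)
    dom <- bp@domains
    # brute-force: every x (role, domain) pairs exactly one y (role,
    # domain) and vice versa
    xd <- dom[dom$class == "x", ]
    keyTo <- paste(xd$partner_role, xd$partner_domain)
    expect_equal(anyDuplicated(keyTo), 0L)
    expect_equal(sort(unique(xd$partner_domain)), 0:(2 * cfg$n - 1))
    yd <- dom[dom$class == "y", ]
    backTo <- paste(yd$partner_role, yd$partner_domain)
    expect_equal(anyDuplicated(backTo), 0L)
    # the maps are mutual inverses
    for (i in sample(nrow(xd), 10)) {
      r <- xd[i, ]
      yrow <- yd[yd$role == r$partner_role & yd$domain == r$partner_domain, ]
      expect_equal(yrow$partner_role, r$role)
      expect_equal(yrow$partner_domain, r$domain)
    }
  }
  expect_error(buildBlueprint(domainLayout(5, 10.5), "half_n_pairs"),
               "even")
})

test_that("assigned sequences are reproducible and base-by-base complementary", {
  bp <- v6Blueprint()
  bp2 <- assignSequences(buildBlueprint(domainLayout(6, 10.5), "full"),
                         rng_seed = 42)
  expect_identical(bp@sequences, bp2@sequences)
  rep <- attr(bp, "constraint_report")
  expect_true(rep$all_crossings_complementary)
  expect_gte(min(rep$min_hamming_by_length), 2)
  expect_gte(rep$gc_range[1], 0.3)
  expect_lte(rep$gc_range[2], 0.7)
  # no homopolymer run of 5 anywhere
  expect_false(any(grepl("A{5}|C{5}|G{5}|T{5}", bp@sequences)))
  # spot-check crossings against the string oracle
  dom <- bp@domains
  xd <- dom[dom$class == "x", ]
  set.seed(1)
  for (i in sample(nrow(xd), 25)) {
    r <- xd[i, ]
    a <- crisscross:::domainSequence(bp, r$slat, r$domain)
    partner <- sprintf("y%02d", r$partner_role)
    b <- crisscross:::domainSequence(bp, partner, r$partner_domain)
    expect_identical(a, revcomp(b))
  }
})

test_that("self-structure scoring agrees with exhaustive search", {
  expect_equal(scoreSelfStructure("AAAAAAAAAA"), 0L)
  expect_gte(scoreSelfStructure("ACGTGCACGT"), 3L)
  expect_equal(scoreSelfStructure(paste0("GCGCG", "CGCGC")), 5L)  # palindrome
  expect_error(scoreSelfStructure("ACGTN"), "only A, C, G, T")
  expect_error(scoreSelfStructure(""), "non-empty")
  set.seed(13)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1),
                      replace = TRUE), collapse = "")
    expect_equal(scoreSelfStructure(s), bruteSelfStructure(s), info = s)
  }
})

test_that("stacking polarity sums the dinucleotide table and flags violations", {
  tab <- stackingTable()
  # hand-computed two-junction check on a tiny fabricated blueprint
  bp <- buildBlueprint(domainLayout(1, 10.5), "full")
  bp@sequences <- c(nucY00 = "AATTAAATTTA", nucY01 = "AATTAAATTTA",
                    x00 = "TACGATCGAT", x01 = "GCATGCATGC",
                    y00 = "AAAAATTTTT", y01 = "CCCGGGCCCG")
  pol <- stackingPolarity(bp)
  # y junctions: y00 domains are 5 + 5 nt -> step "AT"; y01 -> "GG"
  expect_equal(pol$y_total, tab[["AT"]] + tab[["GG"]])
  # x junctions: wrap-around steps "TT" (x00) and "CG" (x01)
  expect_equal(pol$x_total, tab[["TT"]] + tab[["CG"]])
  expect_equal(pol$n_y, 2L)
  # a generated design satisfies the y-over-x polarity by construction
  expect_true(stackingPolarity(v6Blueprint())$polarity_ok)
  expect_error(stackingPolarity(v6Blueprint(), tab[-1]), "incomplete")
  # symmetric toy: identical junction steps in both directions
  bpSym <- bp
  bpSym@sequences[c("y00", "y01")] <- c("AAAAATTTTT", "AAAAATTTTT")
  bpSym@sequences[c("x00", "x01")] <- c("TACGATCGCA", "TACGATCGCA")
  polSym <- stackingPolarity(bpSym)
  expect_equal(polSym$y_mean - polSym$x_mean, 0)
})

test_that("decorations add brushes, paired sticky ends and exact blockers", {
  bp <- v6Blueprint()
  plain <- decorateBlueprint(bp, brush_length = 0)
  expect_identical(plain@sequences, bp@sequences)   # annotation only
  expect_equal(plain@decorations[[1]]$length, 0L)
  dec <- decorateBlueprint(bp, brush_length = 8, brush_end = "3p",
                           sticky_end_length = 3, blockers = c(0, 3))
  expect_true(all(grepl("TTTTTTTT$|[ACG]$",
                        dec@sequences[nucYSlats(dec)])))
  expect_equal(nchar(dec@sequences[["nucY00"]]),
               nchar(bp@sequences[["nucY00"]]) + 8)
  # sticky ends: one edge presents s, the other its reverse complement
  s3 <- substr(dec@sequences[["x00"]], 1, 3)
  end <- dec@sequences[["x00"]]
  expect_equal(substr(end, nchar(end) - 2, nchar(end)), revcomp(s3))
  # blocker is the exact reverse complement of its nucleating y-slat
  expect_equal(dec@sequences[["blocker00"]],
               revcomp(bp@sequences[["nucY00"]]))
  expect_equal(dec@sequences[["blocker03"]],
               revcomp(bp@sequences[["nucY03"]]))
  expect_error(decorateBlueprint(bp, sticky_end_length = 5), "3 or 4")
})

test_that("twist classes follow winding and phase", {
  expect_equal(twistReport(domainLayout(8, 10.5))$coil_class, "flat")
  expect_equal(twistReport(domainLayout(8, 11.0))$coil_class, "tight-coil")
  expect_equal(twistReport(domainLayout(8, 11.0))$winding, "underwound")
  expect_equal(twistReport(domainLayout(8, 10.5, phase = 2))$coil_class,
               "loose-coil")
})

test_that("genome nucleators tile a 190-nt window without gaps or overlaps", {
  genome <- randomGenome(600)
  nx <- designGenomeNucleators(genome, 150, blueprint = v6Blueprint())
  expect_equal(length(nx), 6L)
  til <- attr(nx, "tiling")
  expect_equal(sum(til$genome_end - til$genome_start), 190L)
  expect_equal(til$genome_start[-1], til$genome_end[-6])  # no gaps/overlaps
  # string oracle: concatenated genome-binding domains reconstruct the
  # window by reverse complement
  window <- substr(genome, 151, 340)
  blocks <- vapply(seq_len(6), function(i)
    revcomp(substr(as.character(nx[[i]]), 1,
                   til$genome_end[i] - til$genome_start[i])), "")
  expect_identical(paste(blocks, collapse = ""), window)
  expect_error(designGenomeNucleators(genome, 500,
                                      blueprint = v6Blueprint()),
               "out of range")
  genomeN <- paste0(substr(genome, 1, 200), "N",
                    substr(genome, 202, 600))
  expect_error(designGenomeNucleators(genomeN, 150,
                                      blueprint = v6Blueprint()),
               "ambiguous")
})

test_that("exports are deterministic, parseable and plate-constrained", {
  bp <- v6Blueprint()
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  ex1 <- exportSequences(bp, d1, "v6", repeats = 4)
  ex2 <- exportSequences(bp, d2, "v6", repeats = 4)
  expect_identical(readLines(ex1$fasta), readLines(ex2$fasta))
  expect_identical(readLines(ex1$plate_csv), readLines(ex2$plate_csv))
  # 2n nuc-y + repeats * (u x + u y) records
  fa <- Biostrings::readDNAStringSet(ex1$fasta)
  expect_equal(length(fa), 12 + 4 * (12 + 12))
  # round-trip parse reproduces the sequences exactly
  expect_equal(unname(as.character(fa)[1:12]),
               unname(bp@sequences[nucYSlats(bp)]))
  tab <- ex1$records
  expect_true(all(table(tab$plate) <= 96))
  expect_equal(tab$well[1:9], c("A1", "B1", "C1", "D1", "E1", "F1", "G1",
                                "H1", "A2"))
  expect_equal(max(tab$plate), ceiling(nrow(tab) / 96))
  expect_error(exportSequences(buildBlueprint(domainLayout(6, 10.5),
                                              "full"), tempdir()),
               "assigned")
})
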