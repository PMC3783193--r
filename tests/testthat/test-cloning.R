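notI <- get_enzyme("NotI")

test_that("find_sites locates sites on linear and origin-spanning circular molecules", {
  expect_equal(find_sites(dna_seq("AAGCGGCCGCTT"), notI), 3L)
  expect_equal(find_sites(dna_seq("GGCCGCAAAAGC", topology = "circular"), notI), 11L)
  expect_equal(find_sites(dna_seq("ACGTACGTACGT"), notI), integer(0))
  # brute-force agreement on random sequences with planted sites
  set.seed(21)
  for (i in 1:20) {
    s <- rand_dna(300)
    p <- sample(1:280, 1)
    substr(s, p, p + 7) <- "GCGGCCGC"
    for (topo in c("linear", "circular")) {
      x <- dna_seq(s, topology = topo)
      expect_equal(find_sites(x, notI),
                   sort(oracle_find(s, "GCGGCCGC", circular = topo == "circular")))
    }
  }
})

test_that("digestion conserves sequence content and fragment counts", {
  set.seed(22)
  # linear, 2 sites -> 3 fragments; lengths sum to input + one 4-nt overhang per cut
  s <- paste0(rand_dna(50), "GCGGCCGC", rand_dna(40), "GCGGCCGC", rand_dna(30))
  fr <- digest(dna_seq(s), notI)
  expect_length(fr, 3)
  expect_equal(sum(nchar(vapply(fr, `[[`, "", "seq"))), nchar(s) + 2 * 4)
  # concatenation counting each shared overhang once reconstructs the input
  core <- paste0(fr[[1]]$seq,
                 substr(fr[[2]]$seq, nchar(fr[[2]]$end5) + 1, nchar(fr[[2]]$seq)),
                 substr(fr[[3]]$seq, nchar(fr[[3]]$end5) + 1, nchar(fr[[3]]$seq)))
  expect_identical(core, s)
  # direct string-slicing oracle for the cut positions (GC^GGCCGC)
  p <- oracle_find(s, "GCGGCCGC")
  expect_identical(fr[[1]]$seq, substr(s, 1, p[1] + 5))
  expect_identical(fr[[2]]$seq, substr(s, p[1] + 2, p[2] + 5))
  # linear, no site -> the input back as one blunt fragment
  fr0 <- digest(dna_seq("ACGTACGTACGT"), notI)
  expect_length(fr0, 1)
  expect_identical(fr0[[1]]$seq, "ACGTACGTACGT")
  expect_identical(fr0[[1]]$end5, "")
  # circular with one site -> one fragment of L + overhang, cohesive both ends
  sc <- paste0(rand_dna(46), "GCGGCCGC", rand_dna(46))
  frc <- digest(dna_seq(sc, topology = "circular"), notI)
  expect_length(frc, 1)
  expect_equal(nchar(frc[[1]]$seq), 100 + 4)
  expect_identical(frc[[1]]$end5, "GGCC")
  expect_identical(frc[[1]]$end3, "GGCC")
  expect_error(digest(dna_seq("ACGT", topology = "circular"), notI),
               class = "tagkit_uncut")
})

test_that("digest -> self-ligate -> digest round trips preserve base content", {
  set.seed(23)
  for (enz_name in c("NotI", "HindIII", "XhoI", "EcoRV")) {
    enz <- get_enzyme(enz_name)
    s <- paste0(rand_dna(60), enz$recognition, rand_dna(60))
    circle <- dna_seq(s, topology = "circular")
    frag <- digest(circle, enz)[[1]]
    re <- self_circularize(frag)
    expect_equal(seq_length(re), nchar(s))
    # same circle up to rotation
    expect_true(grepl(re$seq, paste0(s, s), fixed = TRUE))
    # and cutting again yields an identical fragment
    frag2 <- digest(re, enz)[[1]]
    expect_identical(frag2$seq, frag$seq)
  }
})

test_that("self-circularization enforces end compatibility", {
  blunt <- dna_fragment("ACGTACGT")
  expect_equal(seq_length(self_circularize(blunt)), 8)
  mixed <- dna_fragment("GGCCACGTACGT", end5 = "GGCC", end3 = "")
  expect_error(self_circularize(mixed), class = "tagkit_ligation_failure")
})

test_that("PCR reproduces the template in the identity case and enforces specificity", {
  set.seed(24)
  s <- rand_dna(1000)
  tpl <- dna_seq(s)
  fwd <- primer(substr(s, 1, 20), name = "F")
  rev <- primer(revcomp(substr(s, 981, 1000)), name = "R")
  expect_identical(simulate_pcr(tpl, fwd, rev)$seq, s)
  # overhangs are appended verbatim / as reverse complement
  fo <- primer(substr(s, 1, 20), overhang = "CAGTGCGGCCGC", name = "Fo")
  ro <- primer(revcomp(substr(s, 981, 1000)), overhang = "CAGTGCGGCCGC", name = "Ro")
  expect_identical(simulate_pcr(tpl, fo, ro)$seq,
                   paste0("CAGTGCGGCCGC", s, revcomp("CAGTGCGGCCGC")))
  # duplicated binding site -> non-specific priming
  s2 <- paste0(substr(s, 1, 20), rand_dna(100), substr(s, 1, 20), rand_dna(100))
  expect_error(simulate_pcr(dna_seq(s2), primer(substr(s, 1, 20)), rev),
               class = "tagkit_nonspecific_priming")
  # primers facing away on a linear template -> no product
  expect_error(simulate_pcr(tpl, primer(substr(s, 500, 519)),
                            primer(revcomp(substr(s, 100, 119)))),
               class = "tagkit_no_product")
})

test_that("PCR across a circular origin matches the rotated-template oracle", {
  set.seed(25)
  s <- rand_dna(600)
  circ <- dna_seq(s, topology = "circular")
  # amplicon runs 450..600..1..150, spanning the origin
  fwd <- primer(substr(s, 450, 469))
  rev <- primer(revcomp(substr(s, 131, 150)))
  got <- simulate_pcr(circ, fwd, rev)$seq
  rotated <- tagkit:::rotate_string(s, 450)  # now contiguous
  want <- simulate_pcr(dna_seq(rotated), primer(substr(rotated, 1, 20)),
                       primer(revcomp(substr(rotated, 282, 301))))$seq
  expect_identical(got, want)
})

test_that("PCR is strand-symmetric", {
  set.seed(26)
  for (i in 1:20) {
    s <- rand_dna(400)
    tpl <- dna_seq(s)
    a <- sample(1:100, 1); b <- sample(250:380, 1)
    fwd <- primer(substr(s, a, a + 19), overhang = rand_dna(6))
    rev <- primer(revcomp(substr(s, b, b + 19)), overhang = rand_dna(6))
    prod <- simulate_pcr(tpl, fwd, rev)
    flipped <- simulate_pcr(revcomp(tpl), rev, fwd)
    expect_identical(revcomp(prod$seq), flipped$seq)
  }
})

test_that("SLIC assembly joins at the designed overlaps in either orientation", {
  set.seed(27)
  a <- rand_dna(30); b <- rand_dna(30)
  x_core <- rand_dna(400); y_core <- rand_dna(200)
  vec <- dna_seq(paste0(b, x_core, a))           # vector: b-X-a
  ins <- dna_seq(paste0(a, y_core, b))           # insert: a-Y-b
  asm <- slic_assemble(vec, ins)
  expect_equal(c(asm$overlap5, asm$overlap3), c(30, 30))
  expect_equal(seq_length(asm$product), seq_length(vec) + seq_length(ins) - 60)
  expect_true(grepl(paste0(x_core, a, y_core, b), paste0(asm$product$seq, asm$product$seq),
                    fixed = TRUE))
  # reverse-complement insert assembles to the identical circle
  asm_rc <- slic_assemble(vec, revcomp(ins))
  expect_identical(asm_rc$product$seq, asm$product$seq)
  expect_equal(asm_rc$insert_strand, "-")
  # 20-bp overlaps under min_overlap = 25 are rejected
  a20 <- substr(a, 11, 30); b20 <- substr(b, 1, 20)
  vec20 <- dna_seq(paste0(b20, x_core, a20))
  ins20 <- dna_seq(paste0(a20, y_core, b20))
  expect_error(slic_assemble(vec20, ins20, min_overlap = 25),
               class = "tagkit_insufficient_homology")
})

test_that("Cre excision removes the inter-loxP segment and conserves material", {
  lox <- loxp_site()
  set.seed(28)
  for (i in 1:20) {
    A <- rand_dna(sample(20:200, 1)); B <- rand_dna(sample(20:300, 1))
    C <- rand_dna(sample(20:200, 1))
    x <- dna_seq(paste0(A, lox, B, lox, C))
    out <- cre_excise(x)
    expect_identical(out$remaining$seq, paste0(A, lox, C))
    expect_equal(out$excised$topology, "circular")
    expect_true(grepl(paste0(B, lox), paste0(out$excised$seq, out$excised$seq),
                      fixed = TRUE))
    expect_equal(seq_length(out$remaining) + seq_length(out$excised), seq_length(x))
  }
  expect_error(cre_excise(dna_seq(paste0("ACGT", lox, "ACGT"))),
               class = "tagkit_loxp_count")
  expect_error(cre_excise(dna_seq(paste0("ACGT", lox, "AACC", revcomp(lox), "GG"))),
               class = "tagkit_loxp_orientation")
  # a minus-strand pair excises the same segment
  x <- dna_seq(paste0("ACGTAA", lox, "CCGGTT", lox, "AATTGG"))
  flipped <- cre_excise(revcomp(x))
  expect_identical(revcomp(flipped$remaining)$seq, paste0("ACGTAA", lox, "AATTGG"))
})

test_that("HR integration equals a direct three-way string splice", {
  set.seed(29)
  for (i in 1:100) {
    flank5 <- rand_dna(sample(60:150, 1))
    left <- rand_dna(80); right <- rand_dna(80)
    flank3 <- rand_dna(sample(60:150, 1))
    cassette <- rand_dna(sample(100:400, 1))
    genome <- dna_seq(paste0(flank5, left, right, flank3))
    construct <- dna_seq(paste0(left, cassette, right))
    got <- simulate_hr_integration(genome, construct, min_arm = 60)
    expect_identical(got$seq, paste0(flank5, left, cassette, right, flank3))
  }
})

test_that("HR integration rejects scrambled, swapped or missing arms", {
  set.seed(30)
  flank5 <- rand_dna(100); left <- rand_dna(80); right <- rand_dna(80)
  flank3 <- rand_dna(100); cassette <- rand_dna(200)
  genome <- dna_seq(paste0(flank5, left, right, flank3))
  scramble <- paste(sample(strsplit(left, "")[[1]]), collapse = "")
  expect_error(simulate_hr_integration(genome, dna_seq(paste0(scramble, cassette, right)),
                                       min_arm = 60),
               class = "tagkit_targeting_failure")
  expect_error(simulate_hr_integration(genome, dna_seq(paste0(right, cassette, left)),
                                       min_arm = 60),
               class = "tagkit_targeting_failure")
  # tolerated tails: NotI remnants at both termini still integrate
  tailed <- dna_seq(paste0("GGCCGC", left, cassette, right, "GCGGCC"))
  expect_identical(simulate_hr_integration(genome, tailed, min_arm = 60)$seq,
                   paste0(flank5, left, cassette, right, flank3))
})
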