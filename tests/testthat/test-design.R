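test_that("arm extraction brackets the termination codon exactly", {
  b <- design_bundle()
  locus <- b$locus
  arms <- extract_arms(locus, 2500)
  expect_true(substr(arms$right_arm, 1, 3) %in% c("TAA", "TAG", "TGA"))
  # slicing oracle: concatenated arms equal the window centred on the stop
  s <- locus$sequence$seq
  expect_identical(paste0(arms$left_arm, arms$right_arm),
                   substr(s, locus$stop_start - 2500, locus$stop_start + 2499))
  expect_error(extract_arms(locus, 0), class = "tagkit_bad_design")
  err <- tryCatch(extract_arms(locus, 1e6), error = function(e) conditionMessage(e))
  expect_match(err, "maximum feasible arm length is \\d+")
})

test_that("minus-strand loci are normalised to the coding strand", {
  b <- design_bundle()
  plus <- b$locus
  L <- seq_length(plus$sequence)
  minus <- locus_model(revcomp(plus$sequence),
                       stop_start = L - (plus$stop_start + 2) + 1,
                       strand = "-", gene_id = "flipped")
  expect_identical(minus$sequence$seq, plus$sequence$seq)
  expect_equal(minus$stop_start, plus$stop_start)
})

test_that("outer primers add the circularization site and amplify both arms", {
  b <- design_bundle()
  outer <- design_outer_primers(b$locus, 2500)
  expect_match(outer$fwd$overhang, "GCGGCCGC")
  expect_match(outer$rev$overhang, "GCGGCCGC")
  prod <- simulate_pcr(b$locus$sequence, outer$fwd, outer$rev)
  arms <- extract_arms(b$locus, 2500)
  expect_identical(prod$seq, paste0(outer$fwd$overhang, arms$left_arm, arms$right_arm,
                                    revcomp(outer$rev$overhang)))
  # an internal site in the amplified region is refused with alternatives
  s <- b$locus$sequence$seq
  substr(s, b$locus$stop_start - 100, b$locus$stop_start - 93) <- "GCGGCCGC"
  poisoned <- locus_model(dna_seq(s), b$locus$stop_start, gene_id = "poisoned")
  err <- tryCatch(design_outer_primers(poisoned, 2500),
                  error = function(e) conditionMessage(e))
  expect_match(err, "NotI site")
  expect_match(err, "alternatives")
})

test_that("inner primers carry vector-terminal homology and keep the fusion in frame", {
  b <- design_bundle()
  inner <- design_inner_primers(b$locus, b$vec, 2500, overlap = 30)
  lin <- linearize_vector(b$vec)
  lv <- seq_length(lin)
  expect_identical(inner$fwd$overhang, substr(lin$seq, lv - 29, lv))
  expect_identical(inner$rev$overhang, revcomp(substr(lin$seq, 1, 30)))
  # frame oracle: gene CDS end + junction + tag CDS translates with no
  # premature stop before the tag's own stop
  arms <- extract_arms(b$locus, 2500)
  tag <- with(b$vec, substr(sequence$seq, features$start[features$label == "tag_cds"],
                            features$end[features$label == "tag_cds"]))
  cds_tail <- substr(arms$left_arm, nchar(arms$left_arm) - 29, nchar(arms$left_arm))
  junction <- paste0(cds_tail, "AGCTTG", tag)   # 30 nt keeps the native frame
  aa <- translate_dna(junction)
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  expect_true(endsWith(aa, "*"))
})

test_that("the full design chain reproduces the analytic construct and locus", {
  b <- design_bundle()
  d <- b$design
  expect_equal(d$slic_overlaps, c(30, 30))
  # ~10-kb targeting DNA from a ~5-kb vector and 2.5-kb arms
  expect_gt(seq_length(d$construct), 9000)
  expect_lt(seq_length(d$construct), 11000)
  expect_equal(length(find_sites(d$construct, "NotI")), 1)
  # post-Cre tagged locus equals the analytic splice
  expect_identical(d$tagged_locus_post_cre$seq, oracle_post_cre(b$locus, b$vec))
  # fusion protein = natural protein + Ser-Leu junction + tag translation
  tag <- with(b$vec, substr(sequence$seq, features$start[features$label == "tag_cds"],
                            features$end[features$label == "tag_cds"]))
  natural <- translate_dna(substr(b$locus$sequence$seq, b$locus$orf_start,
                                  b$locus$stop_start - 1))
  expect_identical(d$fusion_protein,
                   paste0(natural, "SL", translate_dna(tag, to_stop = TRUE)))
  # pre-Cre locus carries both loxP copies, post-Cre exactly one
  expect_length(tagkit:::find_pattern(d$tagged_locus_pre_cre, loxp_site()), 2)
  expect_length(tagkit:::find_pattern(d$tagged_locus_post_cre, loxp_site()), 1)
})

test_that("verification primers amplify the targeted allele only", {
  b <- design_bundle()
  d <- b$design
  cassette <- with(b$vec, substr(sequence$seq,
                                 features$start[features$label == "selection_cassette"],
                                 features$end[features$label == "selection_cassette"]))
  for (pair in d$verification_primers) {
    # targeted allele: exactly one product
    prod <- simulate_pcr(d$tagged_locus_pre_cre, pair$fwd, pair$rev)
    expect_equal(seq_length(prod), pair$product_bp)
    # wild-type locus: no product from any pair
    expect_error(simulate_pcr(b$locus$sequence, pair$fwd, pair$rev),
                 class = "tagkit_error")
  }
  # the cassette-spanning pair contains the complete selection cassette
  prod1 <- simulate_pcr(d$tagged_locus_pre_cre, d$verification_primers[[1]]$fwd,
                        d$verification_primers[[1]]$rev)
  expect_true(grepl(cassette, prod1$seq, fixed = TRUE))
})

test_that("arm-length bounds are enforced", {
  expect_error(design_config(arm_len = 2000), class = "tagkit_bad_design")
  cfgd <- design_config(arm_len = 2200)
  expect_equal(cfgd$arm_len, 2200)
})

test_that("the designer works across independently seeded loci", {
  for (s in c(7, 19, 33)) {
    cfg <- fixture_config(seed = s)
    locus <- make_locus(cfg)
    vec <- make_vector(cfg)
    d <- design_construct(locus, vec)
    expect_identical(d$tagged_locus_post_cre$seq, oracle_post_cre(locus, vec))
    expect_equal(d$slic_overlaps, c(30, 30))
    expect_false(grepl("\\*", d$fusion_protein))
  }
})
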