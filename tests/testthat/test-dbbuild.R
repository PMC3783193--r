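test_that("a single embedded ORF is found with correct frame and coordinates", {
  set.seed(81)
  orf <- paste0("ATG", paste(sample(setdiff(tagkit:::.sense_codons, "ATG"),
                                    149, replace = TRUE), collapse = ""), "TAA")
  # ATG-free flanks so the planted start codon is the first in its segment
  s <- paste0(strrep("CT", 25), orf, strrep("GA", 20))
  got <- find_orfs(s, min_aa = 100, id = "t1")
  expect_equal(nrow(got), 1)
  expect_equal(got$frame, paste0("+", (50 %% 3) + 1))
  expect_equal(got$start, 51)
  expect_equal(got$end, 50 + 450)        # coding codons, stop excluded
  expect_equal(nchar(got$protein), 150)
  expect_true(startsWith(got$protein, "M"))
})

test_that("an all-stop sequence yields no ORFs", {
  s <- paste(rep("TAATAGTGA", 40), collapse = "")
  expect_equal(nrow(find_orfs(s, min_aa = 5)), 0)
})

test_that("six-frame ORF calls agree with a brute-force oracle on random transcripts", {
  set.seed(82)
  for (i in 1:200) {
    s <- rand_dna(sample(200:600, 1))
    got <- find_orfs(s, min_aa = 20, id = "t")
    want <- oracle_orfs(s, min_aa = 20)
    got_o <- got[order(got$frame, got$start), c("frame", "start", "end", "protein")]
    rownames(got_o) <- rownames(want) <- NULL
    expect_equal(got_o, want)
  }
})

test_that("reverse-complementing a transcript mirrors frames but keeps proteins", {
  set.seed(83)
  for (i in 1:20) {
    s <- rand_dna(500)
    a <- find_orfs(s, min_aa = 20)
    b <- find_orfs(revcomp(s), min_aa = 20)
    expect_setequal(a$protein, b$protein)
    # coordinates map through L - x + 1
    key <- function(d) sort(paste(d$protein, d$start, d$end))
    b_mapped <- data.frame(protein = b$protein, start = 500 - b$end + 1,
                           end = 500 - b$start + 1)
    expect_equal(key(a), key(b_mapped))
  }
})

test_that("annotation keeps the lowest e-value per species with canonical tie-breaks", {
  orfs <- data.frame(orf_id = "t_i1.p1", transcript_id = "t_i1", frame = "+1",
                     start = 1, end = 300, protein = strrep("M", 100),
                     has_stop = TRUE, stringsAsFactors = FALSE)
  hits <- rbind(
    data.frame(query_id = "t_i1.p1", subject_id = "GG_A", pct_identity = 90,
               align_len = 100, mismatches = 1, gap_opens = 0, q_start = 1,
               q_end = 100, s_start = 1, s_end = 100, e_value = 1e-20, bit_score = 80),
    data.frame(query_id = "t_i1.p1", subject_id = "GG_B", pct_identity = 90,
               align_len = 100, mismatches = 1, gap_opens = 0, q_start = 1,
               q_end = 100, s_start = 1, s_end = 100, e_value = 1e-20, bit_score = 95),
    data.frame(query_id = "t_i1.p1", subject_id = "HS_C", pct_identity = 90,
               align_len = 100, mismatches = 1, gap_opens = 0, q_start = 1,
               q_end = 100, s_start = 1, s_end = 100, e_value = 1e-15, bit_score = 60))
  ann <- annotate_orfs(orfs, hits)
  expect_equal(ann$name_chicken, "GG_B")   # equal e-value, higher bit score wins
  expect_equal(ann$name_human, "HS_C")
  # invariant to hit order
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(annotate_orfs(orfs, hits[perm, ])$name_chicken, "GG_B")
  }
  # sub-cutoff hits never annotate
  weak <- hits[1, ]; weak$e_value <- 1e-5
  ann2 <- annotate_orfs(orfs, weak)
  expect_true(is.na(ann2$name_chicken))
  # exact-cutoff ties at equal e-value and bit score: lexicographic subject id
  tie <- rbind(hits[1, ], hits[1, ]); tie$subject_id <- c("GG_Z", "GG_Y")
  expect_equal(annotate_orfs(orfs, tie)$name_chicken, "GG_Y")
})

test_that("representative selection keeps the longest protein per group", {
  ann <- data.frame(
    id = c("B", "A", "C", "solo"),
    protein = c(strrep("M", 200), strrep("M", 200), strrep("M", 120), strrep("M", 90)),
    name_chicken = NA_character_, name_human = NA_character_,
    group_id = c("g1", "g1", "g1", "g2"), stringsAsFactors = FALSE)
  rep <- select_representatives(ann)
  expect_equal(nrow(rep), 2)                       # one per distinct group
  expect_equal(rep$id[rep$group_id == "g1"], "A")  # 200-tie broken by id
  expect_equal(rep$id[rep$group_id == "g2"], "solo")
  # order invariance
  rep2 <- select_representatives(ann[c(3, 1, 4, 2), ])
  expect_equal(rep[order(rep$group_id), ], rep2[order(rep2$group_id), ])
})

test_that("the database FASTA is deterministic with extras appended", {
  tmp1 <- tempfile(fileext = ".fasta"); tmp2 <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tmp1, tmp2)))
  empty <- data.frame(id = character(0), protein = character(0),
                      name_chicken = character(0), name_human = character(0),
                      group_id = character(0), stringsAsFactors = FALSE)
  s1 <- build_fasta_db(empty, tmp1, extras = c(Quant_peptide = "LAADITSLYK",
                                               synthetic_TEV = "MGHHHHHH"))
  expect_equal(s1$n_total, 2)
  fa <- Biostrings::readAAStringSet(tmp1)
  expect_length(fa, 2)
  expect_equal(as.character(fa[[1]]), "LAADITSLYK")
  ann <- data.frame(id = "x.p1", protein = "MKLV", name_chicken = "GG_X",
                    name_human = NA_character_, group_id = "g1",
                    stringsAsFactors = FALSE)
  build_fasta_db(ann, tmp1)
  build_fasta_db(ann, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))   # byte-identical re-run
  expect_match(readLines(tmp1)[1], "x.p1 \\| GG_X \\| - \\| g1")
  dup <- rbind(ann, ann)
  expect_error(build_fasta_db(dup, tmp2), class = "tagkit_duplicate_ids")
})

test_that("the alignment reader tolerates comments and skips malformed rows", {
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  writeLines(c("# comment",
               paste(c("q1", "GG_A", 90, 100, 1, 0, 1, 100, 1, 100, "1e-20", 80),
                     collapse = "\t"),
               "broken\trow",
               paste(c("q1", "HS_B", 90, 100, 1, 0, 1, 100, 1, 100, "not_a_number", 80),
                     collapse = "\t")), p)
  expect_warning(hits <- read_blast_tab(p), class = "tagkit_malformed_hits")
  expect_equal(nrow(hits), 1)
  expect_equal(attr(hits, "n_skipped"), 2)
  expect_equal(hits$e_value, 1e-20)
})

test_that("fixture transcripts recover their planted ground truth end to end", {
  cfg <- fixture_config(seed = 9)
  tr <- make_transcripts(cfg)
  orfs <- do.call(rbind, lapply(tr$transcripts, find_orfs, min_aa = 100))
  ann <- annotate_orfs(orfs, tr$hits)
  rep <- select_representatives(ann)
  truth <- tr$truth[order(tr$truth$group_id), ]
  rep <- rep[order(rep$group_id), ]
  expect_equal(rep$id, truth$orf_id)                 # longest isoform wins
  expect_equal(nchar(rep$protein), truth$aa_len)
  expect_equal(rep$name_chicken, truth$name_chicken) # decoys never annotate
  expect_equal(rep$name_human, truth$name_human)
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  s <- build_fasta_db(rep, tmp)
  expect_equal(s$n_transcript_derived, cfg$n_transcript_groups)
  expect_equal(s$n_without_chicken, sum(is.na(truth$name_chicken)))
})
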