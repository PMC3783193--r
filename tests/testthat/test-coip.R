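mini_table <- function(ints, mw = rep(50, nrow(ints))) {
  proteingroup_table(sprintf("g%02d", seq_len(nrow(ints))), mw, ints)
}

test_that("abundance is mean bait intensity per kDa", {
  tab <- mini_table(matrix(c(2e6, 4e6, 1e6), nrow = 1,
                           dimnames = list(NULL, c("bait_1", "bait_2", "control_1"))),
                    mw = 50)
  expect_equal(compute_abundance(tab, c("bait_1", "bait_2")), 6e4)
  # all-zero -> 0; doubling intensities doubles abundance
  tab0 <- mini_table(matrix(0, 1, 3, dimnames = list(NULL, c("bait_1", "bait_2", "control_1"))))
  expect_equal(compute_abundance(tab0, c("bait_1", "bait_2")), 0)
  tab2 <- mini_table(matrix(c(4e6, 8e6, 2e6), nrow = 1,
                            dimnames = list(NULL, c("bait_1", "bait_2", "control_1"))), mw = 50)
  expect_equal(compute_abundance(tab2, c("bait_1", "bait_2")),
               2 * compute_abundance(tab, c("bait_1", "bait_2")))
  expect_error(proteingroup_table("a", 0, matrix(1, 1, 1, dimnames = list(NULL, "b"))),
               class = "tagkit_bad_table")
})

test_that("specificity is the bait/control ratio with a background floor of 1", {
  ints <- matrix(c(5e6, 5e6, 1e6,    # detected in control: ratio 5
                   5e6, 5e6, 0,      # undetected in control: floor 1 -> 5e6
                   0,   0,   1e6),   # undetected in bait -> 0
                 nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("bait_1", "bait_2", "control_1")))
  tab <- mini_table(ints)
  sp <- compute_specificity(tab, c("bait_1", "bait_2"), "control_1")
  expect_equal(sp, c(5, 5e6, 0))
})

test_that("scores are scale-covariant and order-invariant", {
  set.seed(61)
  ints <- matrix(rlnorm(60, log(1e6), 1), nrow = 20,
                 dimnames = list(NULL, c("bait_1", "bait_2", "control_1")))
  tab <- mini_table(ints, mw = runif(20, 20, 200))
  sc <- score_table(tab, c("bait_1", "bait_2"), "control_1")
  # multiplying all intensities by c leaves specificity fixed, scales abundance
  tabc <- mini_table(ints * 7, mw = tab$mol_weight_kda)
  scc <- score_table(tabc, c("bait_1", "bait_2"), "control_1")
  expect_equal(scc$specificity, sc$specificity)
  expect_equal(scc$abundance, 7 * sc$abundance)
  # permuting rows changes nothing
  perm <- sample(nrow(ints))
  tabp <- proteingroup_table(tab$group_id[perm], tab$mol_weight_kda[perm],
                             ints[perm, ])
  scp <- score_table(tabp, c("bait_1", "bait_2"), "control_1")
  expect_equal(scp, sc)
  # swapping bait and control labels inverts specificity for doubly-detected rows
  one_bait <- ints[, c(1, 3)]
  colnames(one_bait) <- c("bait_1", "control_1")
  tab1 <- mini_table(one_bait, mw = tab$mol_weight_kda)
  fwd <- compute_specificity(tab1, "bait_1", "control_1")
  swapped <- matrix(one_bait[, c(2, 1)], ncol = 2,
                    dimnames = list(NULL, c("bait_1", "control_1")))
  rev <- compute_specificity(mini_table(swapped, mw = tab$mol_weight_kda),
                             "bait_1", "control_1")
  expect_equal(rev, 1 / fwd)
})

test_that("planted interactors top the specificity ranking and are recovered", {
  cfg <- fixture_config(seed = 5)
  pg <- make_proteingroups(cfg)
  sc <- score_table(pg$table, c("bait_1", "bait_2"), "control_1")
  expect_setequal(sc$group_id[1:3], pg$truth$id)
  # parameter recovery: estimated specificity within 25% of the planted
  # enrichment at the fixture's 10% noise level
  est <- sc$specificity[match(pg$truth$id, sc$group_id)]
  ratio <- est / pg$truth$enrichment
  expect_lt(abs(stats::median(ratio) - 1), 0.25)
  expect_true(all(abs(ratio - 1) < 0.4))
})

test_that("the proteinGroups reader round-trips the fixture dialect", {
  cfg <- fixture_config(seed = 6)
  out <- tempfile()
  dir.create(out)
  on.exit(unlink(out, recursive = TRUE))
  write_fixtures(cfg, "coip", out)
  tab <- read_proteingroups(file.path(out, "proteingroups.tsv"))
  direct <- make_proteingroups(cfg)$table
  expect_equal(attr(tab, "runs"), attr(direct, "runs"))
  expect_equal(tab$group_id, direct$group_id)
  expect_equal(tab$bait_1, direct$bait_1, tolerance = 1e-6)
  sc1 <- score_table(tab, c("bait_1", "bait_2"), "control_1")
  sc2 <- score_table(direct, c("bait_1", "bait_2"), "control_1")
  expect_equal(sc1$specificity, sc2$specificity, tolerance = 1e-6)
})

test_that("the scatter file uses log10 axes with NA for zero scores", {
  ints <- matrix(c(1e4, 1e4, 1e2, 0, 0, 5e3), nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, c("bait_1", "bait_2", "control_1")))
  tab <- mini_table(ints)
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  score_table(tab, c("bait_1", "bait_2"), "control_1", scatter_path = p)
  sc <- read.delim(p)
  expect_equal(sc$log10_specificity[sc$group_id == "g01"], 2)
  expect_true(is.na(sc$log10_abundance[sc$group_id == "g02"]))
})
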