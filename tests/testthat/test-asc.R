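AA <- rownames(blosum62())

test_that("the embedded BLOSUM62 matches the Biostrings copy", {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  ref <- env$BLOSUM62[AA, AA]
  expect_equal(unname(blosum62()), unname(ref))
  expect_true(isSymmetric(blosum62()))
})

test_that("worked example: r=A, v=D against two D orthologues scores 8", {
  expect_equal(asc("A", "D", c("D", "D"))$a, 8)
  # s(D,D) = 6, s(A,D) = -2
  expect_equal(blosum62()["D", "D"], 6L)
  expect_equal(blosum62()["A", "D"], -2L)
})

test_that("variant equal to reference scores zero for any panel", {
  set.seed(41)
  for (i in 1:50) {
    r <- sample(AA, 1)
    o <- sample(AA, sample(1:8, 1), replace = TRUE)
    expect_equal(asc(r, r, o)$a, 0)
  }
})

test_that("swapping reference and variant negates the score", {
  set.seed(42)
  for (r in AA) for (v in AA) {
    o <- sample(AA, 3, replace = TRUE)
    expect_equal(asc(r, v, o)$a, -asc(v, r, o)$a)
  }
})

test_that("fully conserved panels never favour the variant", {
  # orthologues all equal to the reference: a = s(v,r) - s(r,r) <= 0
  # for every v != r, because diagonal entries dominate their row
  for (r in AA) for (v in setdiff(AA, r)) {
    expect_lte(asc(r, v, rep(r, 4))$a, 0)
  }
})

test_that("no orthologues means undefined, not zero", {
  res <- asc("A", "D", character(0))
  expect_false(res$defined)
  expect_true(is.na(res$a))
  p <- simulate_orthologue_panels(5, n_species = 0, seed = 2)
  scored <- asc_panels(p)
  expect_true(all(!scored$defined))
})

test_that("nonstandard residues are rejected by name", {
  expect_error(asc("A", "B", c("D")), "B")
  expect_error(asc("A", "D", c("X")), "X")
})

test_that("implementation matches a brute-force oracle on random panels", {
  set.seed(43)
  m <- blosum62()
  for (i in 1:500) {
    r <- sample(AA, 1); v <- sample(AA, 1)
    o <- sample(AA, sample(1:10, 1), replace = TRUE)
    brute <- 0
    for (res in o) brute <- brute + m[v, res] - m[r, res]
    expect_equal(asc(r, v, o)$a, brute / length(o))
  }
})

test_that("panel simulation respects conservation and determinism", {
  p1 <- simulate_orthologue_panels(200, n_species = 10, conservation = 1,
                                   seed = 7)
  expect_true(all(mapply(function(r, o)
    all(strsplit(o, ",")[[1]] == r), p1$ref_aa, p1$orthologue_residues)))
  p2 <- simulate_orthologue_panels(200, n_species = 10, conservation = 1,
                                   seed = 7)
  expect_identical(p1, p2)
  scored <- asc_panels(p1)
  expect_true(all(scored$asc <= 0))   # conserved panels: variant never wins
})

test_that("ASC bins anchor zero on an edge and sum to the input size", {
  rec <- data.frame(asc = c(-4.5, -0.1, 0.1, 2.9, 3.1, 7),
                    heterozygous = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                    shared = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  prof <- asc_bin_profile(rec, bin_width = 3)
  expect_true(0 %in% c(prof$bin_lo, prof$bin_hi))
  expect_equal(sum(prof$count), nrow(rec))
  expect_true(all(prof$bin_hi - prof$bin_lo == 3))
  # all-heterozygous input: every nonempty bin has proportion 1
  rec2 <- rec; rec2$heterozygous <- TRUE
  prof2 <- asc_bin_profile(rec2, 3)
  expect_true(all(prof2$proportion_heterozygous[prof2$count > 0] == 1))
  # empty input
  expect_equal(nrow(asc_bin_profile(rec[0, ], 3)), 0)
})

test_that("a planted conservation-frequency trend shows in the bins", {
  # variants with more negative ASC planted as less often shared: the
  # binned shared proportion should rise with the bin midpoint
  set.seed(44)
  p <- simulate_orthologue_panels(3000, n_species = 8, conservation = 0.85,
                                  seed = 44)
  scored <- asc_panels(p)
  rec <- data.frame(asc = scored$asc,
                    heterozygous = runif(3000) < plogis(-scored$asc / 2),
                    shared = runif(3000) < plogis(scored$asc / 2))
  prof <- asc_bin_profile(rec, 3)
  use <- prof$count >= 30
  mid <- (prof$bin_lo + prof$bin_hi) / 2
  expect_gt(cor(mid[use], prof$proportion_shared[use], method = "spearman"),
            0)
  expect_lt(cor(mid[use], prof$proportion_heterozygous[use],
                method = "spearman"), 0)
})
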