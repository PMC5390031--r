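test_that("expectation scoring matches the stated penalty scheme", {
  mir <- rec("m", "AGACAGUUAUUUUGGGACGGA")   # 21 nt
  rc <- revcomp(mir$sequence, "rna")
  expect_equal(score_site(mir, rc)$expectation, 0)

  # G:U wobble at miRNA position 20 (G): pair it with U instead of C
  w <- strsplit(rc, "")[[1]]
  w[21 - 20 + 1] <- "U"
  sc <- score_site(mir, paste(w, collapse = ""))
  expect_equal(sc$expectation, 0.5)

  # mismatch at position 5 (A, in the doubled seed): penalty 1 x 2
  w <- strsplit(rc, "")[[1]]
  w[21 - 5 + 1] <- "A"
  expect_equal(score_site(mir, paste(w, collapse = ""))$expectation, 2)

  # a gap (deleted target base) costs 2, doubled in seed
  w20 <- strsplit(rc, "")[[1]][-(21 - 20 + 1)]   # drop base pairing pos 20
  expect_equal(score_site(mir, paste(w20, collapse = ""))$expectation, 2)
})

test_that("expectation is zero iff the window is the exact reverse complement", {
  set.seed(12)
  for (i in 1:20) {
    mir <- rec("m", paste(sample(c("A", "C", "G", "U"), 21,
                                 replace = TRUE), collapse = ""))
    rc <- revcomp(mir$sequence, "rna")
    expect_equal(score_site(mir, rc)$expectation, 0)
    w <- strsplit(rc, "")[[1]]
    j <- sample(21, 1)
    w[j] <- sample(setdiff(c("A", "C", "G", "U"), w[j]), 1)
    expect_gt(score_site(mir, paste(w, collapse = ""))$expectation, 0)
  }
})

test_that("dynamic programming equals exhaustive <=1-gap enumeration", {
  set.seed(33)
  for (i in 1:40) {
    m <- sample(18:25, 1)
    mir <- rec("m", paste(sample(c("A", "C", "G", "U"), m,
                                 replace = TRUE), collapse = ""))
    wlen <- m + sample(-1:1, 1)
    w <- paste(sample(c("A", "C", "G", "U"), wlen, replace = TRUE),
               collapse = "")
    expect_equal(score_site(mir, w)$expectation,
                 oracle_score_enum(mir, w),
                 tolerance = 1e-9, info = paste(mir$sequence, w))
  }
})

test_that("scan_targets reports planted sites, honours the cutoff, and maps one-to-many", {
  set.seed(14)
  mir <- rec("mirA", "AGACAGUUAUUUUGGGACGGA")   # pos5=A pos16=G pos20=G
  site <- revcomp(mir$sequence, "rna")
  pad <- function(n) paste(sample(c("C", "A"), n, replace = TRUE),
                           collapse = "")
  tr <- rec("t1", paste0(pad(60), site, pad(60)))
  hits <- scan_targets(list(mir), list(tr))
  perfect <- hits[hits$expectation == 0, ]
  expect_equal(nrow(perfect), 1)
  expect_equal(perfect$t_start, 61)
  expect_equal(perfect$t_end, 81)
  expect_equal(perfect$mode, "cleavage")

  # site engineered to expectation 3.5: seed mismatch at pos 5 (1x2) +
  # mismatch at pos 16 (1) + wobble at pos 20 (0.5); equal window
  # length leaves no gapped alternative
  w <- strsplit(site, "")[[1]]
  L <- 21
  w[L - 5 + 1] <- "A"    # A:A mismatch in the doubled seed
  w[L - 16 + 1] <- "A"   # G:A mismatch outside the seed
  w[L - 20 + 1] <- "U"   # G:U wobble outside the seed
  sc <- score_site(mir, paste(w, collapse = ""))
  expect_equal(sc$expectation, 3.5)
  tr2 <- rec("t2", paste0(pad(30), paste(w, collapse = ""), pad(30)))
  h2 <- scan_targets(list(mir), list(tr2))
  expect_false(any(abs(h2$expectation - 3.5) < 1e-9))

  # one miRNA, five transcripts each carrying one perfect site
  trs <- lapply(1:5, function(i) {
    rec(paste0("t", i), paste0(pad(40), site, pad(40)))
  })
  h5 <- scan_targets(list(mir), trs)
  expect_equal(sum(h5$expectation == 0), 5)
  expect_setequal(unique(h5$transcript_id[h5$expectation == 0]),
                  paste0("t", 1:5))
})

test_that("scores are mirrored under reverse-complement transcript bookkeeping", {
  set.seed(26)
  mir <- rec("m", paste(sample(c("A", "C", "G", "U"), 20,
                               replace = TRUE), collapse = ""))
  tr <- rec("t", paste(sample(c("A", "C", "G", "U"), 80,
                              replace = TRUE), collapse = ""))
  fwd <- scan_targets(list(mir), list(tr), max_expectation = 8)
  rev <- scan_targets(list(mir),
                      list(rec("t", revcomp(tr$sequence, "rna"))),
                      max_expectation = 8)
  n <- nchar(tr$sequence)
  if (nrow(fwd)) {
    mirrored <- data.frame(t_start = n - fwd$t_end + 1,
                           t_end = n - fwd$t_start + 1,
                           expectation = fwd$expectation)
    # every forward site appears (possibly tied) in the reverse scan of
    # the reverse-complemented transcript only if its sequence recurs;
    # expectations at mirrored windows must agree exactly
    for (r in seq_len(nrow(mirrored))) {
      win <- substr(revcomp(tr$sequence, "rna"),
                    mirrored$t_start[r], mirrored$t_end[r])
      expect_equal(score_site(mir, revcomp(win, "rna"))$expectation,
                   score_site(mir, substr(tr$sequence, fwd$t_start[r],
                                          fwd$t_end[r]))$expectation)
    }
  }
  expect_true(TRUE)
})

test_that("inhibition mode follows the central-complementarity rule", {
  mir <- rec("m", "AGACAGUUAUUUUGGGACGGA")   # pos10=U, pos3=A
  rc <- strsplit(revcomp(mir$sequence, "rna"), "")[[1]]
  expect_equal(call_mode(score_site(mir, paste(rc, collapse = ""))),
               "cleavage")

  # U:C mismatch at position 10 blocks slicing
  w <- rc
  w[21 - 10 + 1] <- "C"
  sc <- score_site(mir, paste(w, collapse = ""))
  expect_true(any(sc$columns$type == "mismatch" & sc$columns$mirna_pos == 10))
  expect_equal(call_mode(sc), "translation")

  # wobble at position 3 only: still cleavage
  mir2 <- rec("m2", "UCUUGAAGUCUCGCUUGCAG")  # pos3=U
  rc2 <- strsplit(revcomp(mir2$sequence, "rna"), "")[[1]]
  w2 <- rc2
  w2[20 - 3 + 1] <- "G"                       # U:G wobble
  sc2 <- score_site(mir2, paste(w2, collapse = ""))
  expect_equal(sc2$expectation, 1)            # 0.5 doubled in seed
  expect_equal(call_mode(sc2), "cleavage")
})
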