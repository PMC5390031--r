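test_that("trim_polyAT removes terminal runs and reports counts", {
  r <- trim_polyAT(rec("e", "ACGTAAAAAAAA", "dna"), min_run = 6)
  expect_equal(r$sequence, "ACGT")
  expect_equal(r$trimmed_3p, 8)
  expect_equal(r$trimmed_5p, 0)

  r <- trim_polyAT(rec("e", "TTTTTTTACG", "dna"), min_run = 6)
  expect_equal(r$sequence, "ACG")
  expect_equal(r$trimmed_5p, 7)

  r <- trim_polyAT(rec("e", "ACGTACGT", "dna"), min_run = 6)
  expect_equal(r$sequence, "ACGTACGT")
  expect_equal(r$trimmed_3p + r$trimmed_5p, 0)

  # a long tail may carry sparse interruptions (1 per 10 bases)
  r <- trim_polyAT(rec("e", paste0("ACGT", strrep("A", 12), "G",
                                   strrep("A", 8)), "dna"), min_run = 6)
  expect_equal(r$sequence, "ACGT")

  # consumed entirely
  r <- trim_polyAT(rec("e", "AAAAAAAAAA", "dna"), min_run = 6)
  expect_true(r$dropped)
})

test_that("trimming is idempotent on random tailed reads", {
  set.seed(7)
  for (i in 1:50) {
    core <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
    s <- paste0(strrep("T", sample(0:20, 1)), core,
                strrep("A", sample(0:20, 1)))
    once <- trim_polyAT(rec("e", s, "dna"), min_run = 8)
    if (once$dropped) next
    twice <- trim_polyAT(rec("e", once$sequence, "dna"), min_run = 8)
    expect_equal(twice$sequence, once$sequence)
    expect_equal(twice$trimmed_5p + twice$trimmed_3p, 0)
  }
})

test_that("DUST masking flags simple repeats and spares random sequence", {
  r <- mask_low_complexity(list(id = "x", sequence = "ACACACACACACAC"),
                           window = 12, threshold = 2)
  expect_equal(r$masked_fraction, 1)   # score 20/9 > 2 in every window

  set.seed(3)
  rnd <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
  r <- mask_low_complexity(list(id = "x", sequence = rnd),
                           window = 12, threshold = 2)
  expect_lt(r$masked_fraction, 0.1)

  r <- mask_low_complexity(list(id = "x", sequence = "ACGTACGTACGT"),
                           window = 12, threshold = 100)
  expect_equal(r$masked_fraction, 0)
  expect_error(mask_low_complexity(list(id = "x", sequence = "ACGT"),
                                   window = 3), "window")
})

test_that("deduplicate collapses exact duplicates keeping first ids in order", {
  rs <- list(rec("a", "ACGU"), rec("b", "ACGU"), rec("c", "GGGG"))
  out <- deduplicate(rs)
  expect_equal(vapply(out, `[[`, "", "id"), c("a", "c"))
  expect_equal(deduplicate(list()), list())

  # redundant reference set collapses to its unique sequences
  set.seed(11)
  uniq <- replicate(80, paste(sample(c("A", "C", "G", "U"), 21,
                                     replace = TRUE), collapse = ""))
  uniq <- unique(uniq)
  many <- lapply(seq_len(400), function(i) {
    rec(paste0("m", i), sample(uniq, 1))
  })
  expect_equal(length(deduplicate(many)), length(uniq))
})

test_that("greedy assembly merges overlapping reads into contigs", {
  set.seed(5)
  full <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                collapse = "")
  a <- rec("a", substr(full, 1, 60), "dna")
  b <- rec("b", substr(full, 31, 90), "dna")
  out <- assemble_greedy(list(a, b), min_overlap = 30, min_identity = 0.95)
  expect_length(out, 1)
  expect_equal(out[[1]]$kind, "contig")
  expect_equal(out[[1]]$sequence, full)   # concatenation oracle
  expect_setequal(out[[1]]$member_ids, c("a", "b"))

  # disjoint reads stay singlets
  d1 <- rec("d1", strrep("ACGT", 10), "dna")
  d2 <- rec("d2", strrep("GGCA", 10), "dna")
  out <- assemble_greedy(list(d1, d2))
  expect_setequal(vapply(out, `[[`, "", "kind"), "singlet")

  # three reads tiling a 150-mer reassemble it
  set.seed(6)
  full <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = "")
  reads <- list(rec("r1", substr(full, 1, 70), "dna"),
                rec("r2", substr(full, 41, 110), "dna"),
                rec("r3", substr(full, 81, 150), "dna"))
  out <- assemble_greedy(reads, min_overlap = 30, min_identity = 0.95)
  expect_length(out, 1)
  expect_equal(out[[1]]$sequence, full)
  expect_length(out[[1]]$member_ids, 3)
})

test_that("assembly never invents bases: members are substrings of their contig", {
  set.seed(9)
  for (trial in 1:10) {
    full <- paste(sample(c("A", "C", "G", "T"), sample(120:200, 1),
                         replace = TRUE), collapse = "")
    n_reads <- sample(2:5, 1)
    starts <- sort(sample(seq(1, nchar(full) - 80), n_reads))
    reads <- lapply(seq_len(n_reads), function(i) {
      rec(paste0("r", i), substr(full, starts[i],
                                 min(nchar(full), starts[i] + 79)), "dna")
    })
    out <- assemble_greedy(reads, min_overlap = 20, min_identity = 0.95)
    for (u in out) {
      for (mid in u$member_ids) {
        mseq <- reads[[match(mid, vapply(reads, `[[`, "", "id"))]]$sequence
        expect_true(grepl(mseq, u$sequence, fixed = TRUE))
      }
    }
  }
})

test_that("contaminant screen flags shared 16-mers", {
  cont <- rec("rRNA", strrep("GCTAGGCTAACGTTAG", 3), "dna")
  hit <- rec("u1", paste0("ACGTACGTACGT", substr(cont$sequence, 5, 24)), "dna")
  clean <- rec("u2", strrep("ATCCGA", 10), "dna")
  flags <- screen_contaminants(list(hit, clean), list(cont))
  expect_equal(flags, c(TRUE, FALSE))
  expect_false(any(screen_contaminants(list(hit), NULL)))
})
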