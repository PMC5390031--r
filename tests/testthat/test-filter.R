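test_that("triplet features match hand-enumerated counts", {
  v <- triplet_features(list(sequence = "AAA"), list(structure = "..."))
  expect_equal(unname(v[["A..."]]), 1)
  expect_equal(sum(v), 1)

  v <- triplet_features(list(sequence = "GGGGAAAACCCC"),
                        list(structure = "((((....))))"))
  # 10 interior triples enumerated by hand
  expect_equal(unname(v[["G((("]]), 2 / 10)
  expect_equal(unname(v[["G((."]]), 1 / 10)
  expect_equal(unname(v[["A(.."]]), 1 / 10)
  expect_equal(unname(v[["A..."]]), 2 / 10)
  expect_equal(unname(v[["A..("]]), 1 / 10)
  expect_equal(unname(v[["C.(("]]), 1 / 10)
  expect_equal(unname(v[["C((("]]), 2 / 10)
  expect_equal(sum(v), 1)
  expect_error(triplet_features(list(sequence = "AC"),
                                list(structure = "..")), "length")
})

test_that("feature vectors sum to 1 and withstand an oracle recount", {
  set.seed(19)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 60, replace = TRUE),
               collapse = "")
    f <- fold_hairpin(list(sequence = s), min_len = 1)
    v <- triplet_features(list(sequence = s), f)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    # independent recount via string ops
    sym <- ifelse(strsplit(f$structure, "")[[1]] == ".", ".", "(")
    keys <- vapply(2:59, function(j) {
      paste0(substr(s, j, j), sym[j - 1], sym[j], sym[j + 1])
    }, "")
    recount <- table(keys) / length(keys)
    expect_equal(unname(v[names(recount)]), unname(as.numeric(recount)))
  }
})

test_that("classifier separates planted hairpins from shuffles and is deterministic", {
  model <- shared_model()
  held <- make_training_set(n_pos = 25, n_neg = 25, seed = 99)
  labp <- vapply(held$pos, function(v) classify_hairpin(v, model)$label, "")
  labn <- vapply(held$neg, function(v) classify_hairpin(v, model)$label, "")
  acc <- (sum(labp == "real") + sum(labn == "pseudo")) / 50
  expect_gte(acc, 0.9)

  ts <- make_training_set(n_pos = 20, n_neg = 20, seed = 5)
  m1 <- train_classifier(ts$pos, ts$neg, seed = 5)
  m2 <- train_classifier(ts$pos, ts$neg, seed = 5)
  expect_identical(m1$digest, m2$digest)

  # indistinguishable classes are at chance
  mix <- train_classifier(ts$pos, ts$pos, seed = 5)
  lab <- vapply(ts$pos, function(v) classify_hairpin(v, mix)$label, "")
  expect_equal(mean(lab == "real"), 0.5, tolerance = 0.25)

  expect_error(classify_hairpin(held$pos[[1]], list()), "state error")
  expect_error(train_classifier(ts$pos[1:5], ts$neg, seed = 1), ">= 20")
})

test_that("linear decision margin crosses the boundary monotonically", {
  model <- shared_model()
  held <- make_training_set(n_pos = 5, n_neg = 5, seed = 123)
  mp <- vapply(held$pos, function(v) classify_hairpin(v, model)$margin, 0)
  mn <- vapply(held$neg, function(v) classify_hairpin(v, model)$margin, 0)
  expect_true(any(mp > 0) && any(mn < 0))
  a <- held$pos[[which(mp > 0)[1]]]
  b <- held$neg[[which(mn < 0)[1]]]
  ts <- seq(0, 1, by = 0.1)
  margins <- vapply(ts, function(t) {
    classify_hairpin((1 - t) * a + t * b, model)$margin
  }, numeric(1))
  expect_equal(margins, sort(margins, decreasing = margins[1] > margins[11]),
               tolerance = 1e-8)
  expect_equal(sum(diff(sign(margins)) != 0), 1)
})

test_that("coding/contaminant exclusion drops ORFs and shared 16-mers", {
  set.seed(8)
  # ATG + 70 sense codons (no stop) + stop, as RNA
  body <- paste(replicate(70, {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "U"), 3, replace = TRUE),
                  collapse = "")
      if (!cd %in% c("UAA", "UAG", "UGA")) break
    }
    cd
  }), collapse = "")
  orf <- paste0("AUG", body, "UAA")
  ex <- exclude_coding(list(sequence = paste0("ACGU", orf, "ACGU")))
  expect_false(ex$keep)
  expect_equal(ex$reason, "orf")

  cont <- rec("rRNA", strrep("GCTAGGCTAACGTTAG", 2), "dna")
  p <- list(sequence = chartr("T", "U", paste0("ACGUACGUAC",
                                               substr(cont$sequence, 1, 16))))
  ex <- exclude_coding(p, list(cont))
  expect_false(ex$keep)
  expect_equal(ex$reason, "contaminant")

  clean <- gen_hairpin_precursor(rec("m", strrep("ACGU", 5)), seed = 3)
  expect_true(exclude_coding(clean, list(cont))$keep)
})

test_that("curation passes planted hairpins and fails star-heavy or loop-spanning matures", {
  set.seed(4)
  mat <- rec("m1", paste(sample(c("A", "C", "G", "U"), 21,
                               replace = TRUE), collapse = ""))
  p <- gen_hairpin_precursor(mat, seed = 31)
  f <- fold_hairpin(p)
  st <- hairpin_stats(p, f)
  cv <- curate(p, f, st)
  expect_true(cv$passed)
  expect_equal(cv$star_mismatches, 0)

  # seven unpairable star positions exceed the default cap of six
  p7 <- gen_hairpin_precursor(mat, mutations_in_star = 7, seed = 31)
  f7 <- fold_hairpin(p7)
  cv7 <- curate(p7, f7, hairpin_stats(p7, f7))
  expect_gte(cv7$star_mismatches, 7)
  expect_false(cv7$passed)

  # mature spanning the terminal loop is rejected
  ploop <- p
  mid <- p$mature_end + 4   # inside the loop
  ploop$mature_start <- mid - 5
  ploop$mature_end <- mid + 5
  cvl <- curate(ploop, f, st)
  expect_false(cvl$in_one_arm)
  expect_false(cvl$passed)
})

test_that("the published candidates' AU% and |MFEI| pass the default curation window", {
  t1 <- table1_rows()
  for (r in seq_len(nrow(t1))) {
    p <- list(sequence = seq_with_gc(t1$length[r], t1$gc_count[r]))
    st <- hairpin_stats(p, list(mfe = t1$mfe[r]))
    expect_true(st$au_percent >= 30 && st$au_percent <= 70)
    expect_gte(abs(st$mfei), 0.5)
  }
})

test_that("curation is monotone: relaxing thresholds never converts passed to failed", {
  set.seed(44)
  for (i in 1:8) {
    mat <- rec("m", paste(sample(c("A", "C", "G", "U"), 21,
                                 replace = TRUE), collapse = ""))
    p <- gen_hairpin_precursor(mat, mutations_in_star = sample(0:7, 1),
                               seed = 100 + i)
    f <- fold_hairpin(p)
    st <- hairpin_stats(p, f)
    strict <- curate(p, f, st, max_star_mismatch = 3, au_lo = 40,
                     au_hi = 60, min_abs_mfei = 0.8)
    relaxed <- curate(p, f, st, max_star_mismatch = 10, au_lo = 0,
                      au_hi = 100, min_abs_mfei = 0)
    if (strict$passed) expect_true(relaxed$passed)
  }
})
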