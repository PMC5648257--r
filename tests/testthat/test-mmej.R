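test_that("the worked microhomology example predicts the expected deletion", {
  amp <- amplicon("AAGAGTTTGAGCC", cut_after = 7, target_start = 6,
                  target_end = 8)
  out <- enumerate_mmej(amp, min_mh = 3, max_del = 10)
  expect_equal(nrow(out), 1)
  expect_equal(out$mh, "GAG")
  expect_equal(out$arm1_start, 3)
  expect_equal(out$arm2_start, 9)
  expect_equal(out$del_length, 6)
  # annealing the arms removes the intervening bases; leftmost label
  expect_equal(out$label, "3-GAGTTT")
  expect_equal(out$frame_class, "in-frame")
})

test_that("sequences without repeats near the cut yield no candidates", {
  amp <- amplicon("ACGTACGGTTAACCGGATCG", cut_after = 10, target_start = 9,
                  target_end = 11)
  # min_mh = 5 exceeds any repeated k-mer across this cut
  expect_equal(nrow(enumerate_mmej(amp, min_mh = 5, max_del = 20)), 0)
  expect_error(enumerate_mmej(amp, min_mh = 1), ">= 2")
})

test_that("a repeat spanning the cut predicts an in-frame allele", {
  #          1234567890123456789012
  seq <- "AACCGTAGCATAGCTTACCGAT"
  #       arms ATAGC? plant: GTAGC at 5-9 and 11-15 is 'TAGC'..; use exact:
  seq <- "AACCGTAGCATGTAGCTTACCGAT"
  # arms "GTAGC" at 5-9 and 12-16, cut after 10: deletion = 12-5 = 7 bp
  amp <- amplicon(seq, cut_after = 10, target_start = 9, target_end = 11)
  out <- enumerate_mmej(amp, min_mh = 4, max_del = 20)
  expect_true(any(out$mh_length >= 4 & out$del_length == 7))
  # 3-bp arms giving a multiple-of-3 deletion are classified in-frame
  expect_equal(out$frame_class, ifelse(out$del_length %% 3 == 0,
                                       "in-frame", "frameshift"))
})

test_that("enumeration equals exhaustive brute force on random short sequences", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(30:60, 1)
    cut <- sample(10:(n - 10), 1)
    ref <- random_dna(n)
    amp <- amplicon(ref, cut_after = cut, target_start = cut - 1,
                    target_end = cut + 1)
    min_mh <- sample(2:3, 1)
    max_del <- sample(c(15, 30, 50), 1)
    got <- sort(enumerate_mmej(amp, min_mh, max_del)$label)
    want <- brute_mmej_labels(ref, cut, min_mh, max_del)
    expect_equal(got, want)
  }
})

test_that("deduplication keeps the longest microhomology per resulting allele", {
  # 'CACA' arms contain nested 'CA'/'ACA' arms that collapse to the same
  # deletion; only one candidate per label, with the maximal arm recorded
  seq <- paste0(strrep("G", 6), "CACA", "TTT", "CACA", strrep("G", 6))
  amp <- amplicon(seq, cut_after = 11, target_start = 10, target_end = 12)
  out <- enumerate_mmej(amp, min_mh = 2, max_del = 20)
  expect_false(any(duplicated(out$label)))
  lab7 <- out[out$del_length == 7, ]
  if (nrow(lab7)) expect_true(all(lab7$mh_length >= 2))
})
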