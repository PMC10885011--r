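test_that("synthetic generation is seeded, bounded and uses only A/C/G/T", {
  spec <- synthetic_spec(n_per_class = 0, length = 50, seed = 7)
  expect_equal(nrow(generate_identification_dataset(spec)), 0)

  spec <- synthetic_spec(n_per_class = 25, length = 60, seed = 7,
                         homopolymer_boost = 0.4)
  a <- generate_identification_dataset(spec)
  b <- generate_identification_dataset(spec)
  expect_identical(a, b)
  expect_false(any(grepl("[^ACGT]", a$seq)))
  expect_equal(nchar(a$seq), rep(60, 50))

  expect_error(synthetic_spec(10, gc_positive = 1.2), "strictly in")
  expect_error(synthetic_spec(-1), "non-negative")
})

test_that("positive-class GC fraction concentrates on gc_positive", {
  ds <- generate_identification_dataset(
    synthetic_spec(n_per_class = 1000, length = 200, gc_positive = 0.6,
                   gc_negative = 0.4, seed = 11))
  gc_pos <- mean(gc_fraction(ds$seq[ds$layer1 == "enhancer"]))
  expect_lt(abs(gc_pos - 0.6), 0.01)
  gc_neg <- mean(gc_fraction(ds$seq[ds$layer1 == "non_enhancer"]))
  expect_lt(abs(gc_neg - 0.4), 0.01)
})

test_that("a two-proportion test separates classes at a 0.2 GC gap", {
  ds <- generate_strength_dataset(
    synthetic_spec(n_per_class = 1000, length = 100, gc_positive = 0.6,
                   gc_negative = 0.4, seed = 5))
  expect_true(all(ds$layer1 == "enhancer"))
  expect_equal(as.vector(table(ds$layer2)), c(1000, 1000))
  counts <- vapply(split(ds$seq, ds$layer2), function(s)
    sum(unlist(strsplit(s, "")) %in% c("G", "C")), 1)
  totals <- vapply(split(ds$seq, ds$layer2), function(s)
    sum(nchar(s)), 1)
  pt <- prop.test(counts, totals)
  expect_lt(pt$p.value, 0.001)
})

test_that("homopolymer boost plants an AA/TT dinucleotide excess", {
  spec <- synthetic_spec(n_per_class = 300, length = 100, gc_positive = 0.5,
                         gc_negative = 0.5, homopolymer_boost = 0.6, seed = 9)
  ds <- generate_identification_dataset(spec)
  run_rate <- function(seqs) {
    dimers <- unlist(lapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      paste0(ch[-length(ch)], ch[-1])
    }))
    mean(dimers %in% c("AA", "TT"))
  }
  expect_gt(run_rate(ds$seq[ds$layer1 == "non_enhancer"]),
            run_rate(ds$seq[ds$layer1 == "enhancer"]) + 0.02)
})

test_that("composition report normalizes per position and sees the GC signal", {
  one <- benchmark_dataset("x", "AAAA", "enhancer", "not_applicable")
  rep1 <- composition_report(one)
  expect_equal(unname(rep1$enhancer[, "A"]), rep(1, 4))

  ds <- generate_identification_dataset(
    synthetic_spec(n_per_class = 400, length = 120, gc_positive = 0.6,
                   gc_negative = 0.4, seed = 2))
  rep2 <- composition_report(ds)
  for (cl in names(rep2)) {
    expect_lt(max(abs(rowSums(rep2[[cl]]) - 1)), 1e-12)
  }
  gc_by_pos_pos <- rowSums(rep2$enhancer[, c("G", "C")])
  gc_by_pos_neg <- rowSums(rep2$non_enhancer[, c("G", "C")])
  expect_gt(mean(gc_by_pos_pos > gc_by_pos_neg), 0.95)

  ragged <- benchmark_dataset(c("a", "b"), c("ACGT", "ACG"),
                              rep("enhancer", 2), rep("not_applicable", 2))
  expect_error(composition_report(ragged), "equal-length")
})

test_that("widening the GC gap cannot reduce GC-threshold separability", {
  aurocs <- vapply(c(0, 0.08, 0.2), function(gap) {
    ds <- generate_identification_dataset(
      synthetic_spec(n_per_class = 400, length = 150,
                     gc_positive = 0.5 + gap / 2,
                     gc_negative = 0.5 - gap / 2, seed = 31))
    compute_metrics(enhancerlm:::dataset_y(ds), gc_fraction(ds$seq))$AUROC
  }, 1)
  expect_true(all(diff(aurocs) > -1e-9))
  expect_gt(aurocs[3], 0.99)
})
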