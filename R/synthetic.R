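# Synthetic dataset generator.
#
# Emulates the compositional class structure reported for the two-layer
# enhancer benchmark: the positive class (enhancers / strong enhancers) is
# GC-enriched, the negative class (non-enhancers / weak enhancers) is
# AT-enriched and may additionally carry an excess of AA/TT homopolymer runs
# via a first-order Markov boost of A->A and T->T transitions.

#' Specification for a synthetic two-class DNA dataset
#'
#' @param n_per_class Sequences per class.
#' @param length Sequence length in residues (the benchmark uses 200 bp).
#' @param gc_positive Probability of drawing G or C at each position of a
#'   positive-class sequence (split evenly between G and C).
#' @param gc_negative Same for the negative class.
#' @param homopolymer_boost Relative excess weight (>= 0) on extending an A
#'   or T run in the negative class: after an A, the probability of another A
#'   is multiplied by `1 + homopolymer_boost` (then renormalized); likewise
#'   for T. `0` gives i.i.d. residues.
#' @param seed Integer seed; identical specs generate identical datasets.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class, length = 200L, gc_positive = 0.60,
                           gc_negative = 0.40, homopolymer_boost = 0,
                           seed = 1L) {
  if (!is.numeric(n_per_class) || n_per_class < 0)
    stopf("n_per_class must be a non-negative count")
  if (length < 1) stopf("length must be positive")
  if (gc_positive <= 0 || gc_positive >= 1 || gc_negative <= 0 || gc_negative >= 1)
    stopf("gc_positive and gc_negative must lie strictly in (0, 1)")
  if (homopolymer_boost < 0) stopf("homopolymer_boost must be >= 0")
  structure(list(n_per_class = as.integer(n_per_class),
                 length = as.integer(length),
                 gc_positive = gc_positive, gc_negative = gc_negative,
                 homopolymer_boost = homopolymer_boost,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Draw n sequences of given length. Base composition is i.i.d. with
# P(G)=P(C)=gc/2; when boost > 0 a first-order Markov kernel multiplies the
# weight of A->A and T->T transitions by (1 + boost). Vectorized across
# sequences, looping over positions.
draw_sequences <- function(n, length, gc, boost = 0) {
  if (n == 0) return(character(0))
  base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  letters4 <- names(base)
  upper <- upper.tri(matrix(0, 4, 4), diag = TRUE) * 1
  sample_from <- function(prob_matrix) {
    # prob_matrix: n x 4 row-stochastic; one inverse-CDF draw per row
    u <- stats::runif(nrow(prob_matrix))
    cum <- prob_matrix %*% upper
    idx <- rowSums(u > cum) + 1L
    letters4[idx]
  }
  out <- matrix("", nrow = n, ncol = length)
  probs <- matrix(base, nrow = n, ncol = 4, byrow = TRUE)
  out[, 1] <- sample_from(probs)
  if (length > 1) {
    # Transition rows conditioned on previous residue
    trans <- matrix(base, nrow = 4, ncol = 4, byrow = TRUE,
                    dimnames = list(letters4, letters4))
    if (boost > 0) {
      trans["A", "A"] <- trans["A", "A"] * (1 + boost)
      trans["T", "T"] <- trans["T", "T"] * (1 + boost)
      trans <- trans / rowSums(trans)
    }
    for (p in 2:length) {
      prev <- match(out[, p - 1], letters4)
      out[, p] <- sample_from(trans[prev, , drop = FALSE])
    }
  }
  apply(out, 1, paste, collapse = "")
}

#' Generate a synthetic enhancer-identification dataset
#'
#' Positive class ("enhancer"): i.i.d. residues with GC probability
#' `gc_positive`. Negative class ("non_enhancer"): GC probability
#' `gc_negative` plus the optional A/T homopolymer-run boost.
#'
#' @param spec A [synthetic_spec()].
#' @return A [benchmark_dataset()] with `task = "identification"`.
#' @export
generate_identification_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    pos <- draw_sequences(spec$n_per_class, spec$length, spec$gc_positive)
    neg <- draw_sequences(spec$n_per_class, spec$length, spec$gc_negative,
                          spec$homopolymer_boost)
  })
  n <- spec$n_per_class
  benchmark_dataset(
    ids = c(sprintf("enh_%04d", seq_len(n)), sprintf("non_%04d", seq_len(n))),
    seqs = c(pos, neg),
    layer1 = rep(c("enhancer", "non_enhancer"), each = n),
    layer2 = rep("not_applicable", 2 * n),
    task = "identification", split = "core")
}

#' Generate a synthetic enhancer-strength dataset
#'
#' Both classes are enhancers at layer 1; "strong" uses `gc_positive`,
#' "weak" uses `gc_negative` plus the homopolymer boost.
#'
#' @param spec A [synthetic_spec()].
#' @return A [benchmark_dataset()] with `task = "strength"`.
#' @export
generate_strength_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    strong <- draw_sequences(spec$n_per_class, spec$length, spec$gc_positive)
    weak <- draw_sequences(spec$n_per_class, spec$length, spec$gc_negative,
                           spec$homopolymer_boost)
  })
  n <- spec$n_per_class
  benchmark_dataset(
    ids = c(sprintf("str_%04d", seq_len(n)), sprintf("wea_%04d", seq_len(n))),
    seqs = c(strong, weak),
    layer1 = rep("enhancer", 2 * n),
    layer2 = rep(c("strong", "weak"), each = n),
    task = "strength", split = "core")
}

#' Position-wise nucleotide composition per class
#'
#' For each class and sequence position, the frequency of each of A/C/G/T
#' (N counts are excluded from the normalization denominator).
#'
#' @param dataset A non-empty [benchmark_dataset()] of equal-length sequences.
#' @return A named list, one `positions x 4` frequency matrix per class;
#'   each row sums to 1.
#' @export
composition_report <- function(dataset) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  if (nrow(dataset) == 0) stopf("dataset is empty")
  lens <- nchar(dataset$seq)
  if (length(unique(lens)) != 1)
    stopf("composition_report requires equal-length sequences (saw lengths %s)",
          paste(sort(unique(lens)), collapse = ", "))
  labels <- dataset_labels(dataset)
  L <- lens[1]
  out <- lapply(split(dataset$seq, labels), function(seqs) {
    chars <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                    nrow = length(seqs), byrow = TRUE)
    freq <- sapply(c("A", "C", "G", "T"), function(b) colMeans(chars == b))
    freq / rowSums(freq)
  })
  out
}
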