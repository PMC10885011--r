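# K-mer tokenization and vocabulary handling.
#
# Sequences are segmented into overlapping k-mers at stride 1 (a length-L
# sequence yields L - k + 1 tokens). The vocabulary maps k-mer strings to
# dense integer ids; three special tokens (<pad>, <unk>, <bos>) come first.
# K-mers containing N, or unseen at vocabulary-building time, map to <unk>.

PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"
BOS_TOKEN <- "<bos>"
SPECIAL_TOKENS <- c(PAD_TOKEN, UNK_TOKEN, BOS_TOKEN)

#' Segment a DNA sequence into overlapping k-mers
#'
#' @param sequence A single sequence string.
#' @param k K-mer size, `1 <= k <= nchar(sequence)`.
#' @param stride Window step; the default 1 gives overlapping k-mers.
#' @return Character vector of `floor((L - k) / stride) + 1` k-mers, left to
#'   right.
#' @examples
#' kmerize("ACTAGGA", 3)  # "ACT" "CTA" "TAG" "AGG" "GGA"
#' @export
kmerize <- function(sequence, k, stride = 1L) {
  stopifnot(length(sequence) == 1)
  L <- nchar(sequence)
  if (k < 1) stopf("k must be >= 1")
  if (k > L) stopf("k = %d exceeds sequence length %d", k, L)
  if (stride < 1) stopf("stride must be >= 1")
  starts <- seq.int(1L, L - k + 1L, by = stride)
  substring(sequence, starts, starts + k - 1L)
}

#' Build a k-mer vocabulary from a corpus
#'
#' Contains every distinct k-mer observed in the corpus (sorted, so id
#' assignment is reproducible) plus the special tokens `<pad>`, `<unk>`,
#' `<bos>` at ids 1..3. With `full = TRUE` all 4^k k-mers over A/C/G/T are
#' enumerated instead.
#'
#' @param corpus Character vector of sequences (named or not).
#' @param k K-mer size.
#' @param full Enumerate the complete 4^k alphabet instead of the observed
#'   k-mers.
#' @return An object of class `kmer_vocab` with fields `k`, `tokens`
#'   (id-ordered), `size`, and the special-token ids `pad_id`, `unk_id`,
#'   `bos_id`.
#' @export
build_vocabulary <- function(corpus, k, full = FALSE) {
  if (k < 1) stopf("k must be >= 1")
  if (full) {
    kmers <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                    stringsAsFactors = FALSE),
                        1, paste, collapse = ""))
  } else {
    if (length(corpus) == 0) {
      warnf("empty corpus: vocabulary contains only special tokens")
      kmers <- character(0)
    } else {
      usable <- corpus[nchar(corpus) >= k]
      observed <- unlist(lapply(usable, kmerize, k = k), use.names = FALSE)
      observed <- observed[!grepl("N", observed, fixed = TRUE)]
      kmers <- sort(unique(observed))
    }
  }
  tokens <- c(SPECIAL_TOKENS, kmers)
  structure(list(k = as.integer(k), tokens = tokens,
                 size = length(tokens),
                 pad_id = 1L, unk_id = 2L, bos_id = 3L),
            class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("k-mer vocabulary: k=%d, %d tokens (%d k-mers + %d specials)\n",
              x$k, x$size, x$size - length(SPECIAL_TOKENS),
              length(SPECIAL_TOKENS)))
  invisible(x)
}

#' Convert a sequence to integer token ids
#'
#' K-mers absent from the vocabulary (including any containing N) map to the
#' `<unk>` id; [denumericalize()] inverts the mapping for in-vocabulary
#' sequences.
#'
#' @param sequence A single sequence string.
#' @param vocab A [build_vocabulary()] result.
#' @param bos Prepend the `<bos>` id (used for language-model training so the
#'   first real k-mer has a prediction context).
#' @return Integer vector of token ids, all `<= vocab$size`.
#' @export
numericalize <- function(sequence, vocab, bos = FALSE) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  kmers <- kmerize(sequence, vocab$k)
  ids <- match(kmers, vocab$tokens)
  ids[is.na(ids)] <- vocab$unk_id
  if (bos) ids <- c(vocab$bos_id, ids)
  as.integer(ids)
}

#' Recover k-mer strings from token ids
#'
#' @param ids Integer token ids.
#' @param vocab The vocabulary that produced them.
#' @return Character vector of tokens.
#' @export
denumericalize <- function(ids, vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"), all(ids >= 1), all(ids <= vocab$size))
  vocab$tokens[ids]
}

#' Write a vocabulary as a two-column text file
#' @param vocab A `kmer_vocab`.
#' @param path Output path; each line is `<token> <id>`.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  utils::write.table(
    data.frame(token = vocab$tokens, id = seq_along(vocab$tokens)),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a vocabulary written by [write_vocabulary()]
#' @param path Two-column text file of `<token> <id>` lines.
#' @return A `kmer_vocab`.
#' @export
read_vocabulary <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("token", "id"),
                           stringsAsFactors = FALSE)
  tab <- tab[order(tab$id), , drop = FALSE]
  tokens <- tab$token
  if (!identical(tokens[1:3], SPECIAL_TOKENS))
    stopf("'%s' does not start with the special tokens %s", path,
          paste(SPECIAL_TOKENS, collapse = " "))
  real <- setdiff(tokens, SPECIAL_TOKENS)
  k <- if (length(real)) unique(nchar(real)) else 1L
  if (length(k) != 1) stopf("inconsistent k-mer lengths in '%s'", path)
  structure(list(k = as.integer(k), tokens = tokens, size = length(tokens),
                 pad_id = 1L, unk_id = 2L, bos_id = 3L),
            class = "kmer_vocab")
}
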