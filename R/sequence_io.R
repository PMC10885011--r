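# FASTA input/output and the two-layer benchmark loader.
#
# Sequences are plain named character vectors (names = record ids, values =
# uppercase strings over A/C/G/T/N). Labeled datasets are data frames with
# columns id, seq, layer1, layer2 and class "benchmark_dataset".

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file of DNA sequences
#'
#' Parses a FASTA file, uppercases the residues and validates that every
#' record uses only the A/C/G/T/N alphabet. A zero-byte file yields an empty
#' result; a non-empty file that is not FASTA raises a format error.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector: names are record identifiers, values the
#'   uppercase sequences. Order matches the file.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt", ">s2", "GGCC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: '%s'", path)
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stopf("'%s' is not a readable FASTA file: %s", path,
                              conditionMessage(e))
  )
  if (length(set) == 0) stopf("'%s' contains no FASTA records", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  names(seqs) <- ids
  validate_alphabet(seqs)
  seqs
}

validate_alphabet <- function(seqs) {
  bad <- grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    offender <- names(seqs)[bad][1]
    residues <- setdiff(unique(strsplit(seqs[bad][1], "")[[1]]), DNA_ALPHABET)
    stopf("record '%s' contains residues outside {A,C,G,T,N}: %s",
          offender, paste(residues, collapse = ", "))
  }
  invisible(seqs)
}

#' Write DNA sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences (as returned by
#'   [read_fasta()]). Must be non-empty.
#' @param path Output file path.
#' @param width Line-wrap width for the sequence body.
#' @return `path`, invisibly. `read_fasta(write_fasta(x, p))` restores `x`.
#' @export
write_fasta <- function(sequences, path, width = 80L) {
  if (length(sequences) == 0) stopf("refusing to write an empty FASTA file")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stopf("every sequence needs a non-empty name")
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Construct a labeled benchmark-style dataset
#'
#' @param ids,seqs Character vectors of identifiers and sequences.
#' @param layer1 `"enhancer"` or `"non_enhancer"` per sequence.
#' @param layer2 `"strong"`, `"weak"` or `"not_applicable"` per sequence;
#'   must be `"not_applicable"` exactly when `layer1 == "non_enhancer"`.
#' @param task `"identification"` or `"strength"`.
#' @param split `"core"` or `"independent_test"`.
#' @return A `benchmark_dataset` data frame with columns id, seq, layer1,
#'   layer2.
#' @export
benchmark_dataset <- function(ids, seqs, layer1, layer2,
                              task = c("identification", "strength"),
                              split = c("core", "independent_test")) {
  task <- match.arg(task)
  split <- match.arg(split)
  stopifnot(length(ids) == length(seqs), length(layer1) == length(seqs),
            length(layer2) == length(seqs))
  if (!all(layer1 %in% c("enhancer", "non_enhancer")))
    stopf("layer1 labels must be 'enhancer' or 'non_enhancer'")
  if (!all(layer2 %in% c("strong", "weak", "not_applicable")))
    stopf("layer2 labels must be 'strong', 'weak' or 'not_applicable'")
  if (any(layer1 == "non_enhancer" & layer2 != "not_applicable"))
    stopf("non-enhancers cannot carry a strength label")
  if (any(layer1 == "enhancer" & !layer2 %in% c("strong", "weak", "not_applicable")))
    stopf("invalid layer2 label for an enhancer")
  ds <- data.frame(id = as.character(ids), seq = toupper(as.character(seqs)),
                   layer1 = layer1, layer2 = layer2,
                   stringsAsFactors = FALSE, row.names = NULL)
  attr(ds, "task") <- task
  attr(ds, "split") <- split
  class(ds) <- c("benchmark_dataset", "data.frame")
  ds
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("Benchmark dataset: %d sequences (task=%s, split=%s)\n",
              nrow(x), attr(x, "task"), attr(x, "split")))
  lab <- dataset_labels(x)
  print(table(lab))
  invisible(x)
}

# The binary label relevant to the dataset's task: layer1 for identification,
# layer2 for strength.
dataset_labels <- function(dataset) {
  if (identical(attr(dataset, "task"), "strength")) dataset$layer2 else dataset$layer1
}

# Positive class per task ("enhancer" / "strong"); returns 0/1 integer vector.
dataset_y <- function(dataset) {
  lab <- dataset_labels(dataset)
  pos <- if (identical(attr(dataset, "task"), "strength")) "strong" else "enhancer"
  as.integer(lab == pos)
}

# Canonical benchmark file layout: one FASTA per class per split plus a
# MANIFEST mapping file -> task, split, label. See load_benchmark().
BENCHMARK_MANIFEST <- "MANIFEST"

# Published structure of the Liu et al. 2016 two-layer benchmark, used only
# to emit a validation warning when supplied files disagree with it.
BENCHMARK_EXPECTED <- list(
  identification_core = c(enhancer = 1484L, non_enhancer = 1484L),
  strength_core = c(strong = 742L, weak = 742L),
  strength_independent_test = c(strong = 100L, weak = 100L)
)

#' Load the two-layer enhancer benchmark from a directory
#'
#' Expects a directory holding one FASTA file per class per split plus a
#' `MANIFEST` text file with one whitespace-separated line per FASTA:
#' `<file> <task> <split> <label>`, where task is
#' `identification`/`strength`, split is `core`/`independent_test` and label
#' is `enhancer`/`non_enhancer`/`strong`/`weak`. [write_benchmark()] emits
#' this layout. Class counts are validated against the published dataset
#' structure with a warning (never an error) on mismatch; for the independent
#' identification split the loader reports whatever files the manifest lists
#' (a non-enhancer file is optional).
#'
#' @param dir Directory containing the FASTA files and manifest.
#' @param task `"identification"` or `"strength"`.
#' @param split `"core"` or `"independent_test"`.
#' @return A [benchmark_dataset()].
#' @export
load_benchmark <- function(dir, task = c("identification", "strength"),
                           split = c("core", "independent_test")) {
  task <- match.arg(task)
  split <- match.arg(split)
  manifest_path <- file.path(dir, BENCHMARK_MANIFEST)
  if (!dir.exists(dir) || !file.exists(manifest_path)) {
    stopf(paste0(
      "benchmark not installed: expected directory '%s' with a '%s' file ",
      "(one line per FASTA: <file> <task> <split> <label>). ",
      "If the external benchmark is unavailable, generate a synthetic ",
      "stand-in with generate_identification_dataset() / ",
      "generate_strength_dataset() or write_benchmark()."), dir, BENCHMARK_MANIFEST)
  }
  man <- utils::read.table(manifest_path, header = FALSE,
                           col.names = c("file", "task", "split", "label"),
                           stringsAsFactors = FALSE)
  man <- man[man$task == task & man$split == split, , drop = FALSE]
  if (nrow(man) == 0)
    stopf("manifest in '%s' lists no files for task=%s split=%s", dir, task, split)
  pieces <- lapply(seq_len(nrow(man)), function(i) {
    fp <- file.path(dir, man$file[i])
    if (!file.exists(fp))
      stopf("benchmark not installed: manifest names missing file '%s'", fp)
    seqs <- read_fasta(fp)
    label <- man$label[i]
    if (task == "identification") {
      layer1 <- rep(label, length(seqs))
      layer2 <- rep("not_applicable", length(seqs))
    } else {
      layer1 <- rep("enhancer", length(seqs))
      layer2 <- rep(label, length(seqs))
    }
    list(ids = names(seqs), seqs = unname(seqs), layer1 = layer1, layer2 = layer2)
  })
  ds <- benchmark_dataset(
    ids = unlist(lapply(pieces, `[[`, "ids")),
    seqs = unlist(lapply(pieces, `[[`, "seqs")),
    layer1 = unlist(lapply(pieces, `[[`, "layer1")),
    layer2 = unlist(lapply(pieces, `[[`, "layer2")),
    task = task, split = split)
  counts <- table(dataset_labels(ds))
  message(sprintf("loaded %d sequences (%s)", nrow(ds),
                  paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                        collapse = ", ")))
  key <- paste(task, split, sep = "_")
  expected <- BENCHMARK_EXPECTED[[key]]
  if (!is.null(expected)) {
    got <- as.integer(counts[names(expected)])
    got[is.na(got)] <- 0L
    if (!all(got == expected)) {
      warnf("class counts (%s) differ from the published benchmark (%s)",
            paste(sprintf("%s=%d", names(expected), got), collapse = ", "),
            paste(sprintf("%s=%d", names(expected), expected), collapse = ", "))
    }
  }
  ds
}

#' Write a dataset as a benchmark-layout directory
#'
#' Emits one FASTA per class plus the `MANIFEST` file understood by
#' [load_benchmark()].
#'
#' @param dataset A [benchmark_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(dataset, dir) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  task <- attr(dataset, "task")
  split <- attr(dataset, "split")
  labels <- dataset_labels(dataset)
  man <- NULL
  for (label in unique(labels)) {
    sel <- labels == label
    fname <- sprintf("%s_%s_%s.fa", task, split, label)
    write_fasta(stats::setNames(dataset$seq[sel], dataset$id[sel]),
                file.path(dir, fname))
    man <- rbind(man, data.frame(file = fname, task = task, split = split,
                                 label = label, stringsAsFactors = FALSE))
  }
  manifest_path <- file.path(dir, BENCHMARK_MANIFEST)
  exists_old <- if (file.exists(manifest_path)) {
    utils::read.table(manifest_path, header = FALSE,
                      col.names = c("file", "task", "split", "label"),
                      stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(exists_old)) {
    keep <- !(exists_old$task == task & exists_old$split == split)
    man <- rbind(exists_old[keep, , drop = FALSE], man)
  }
  utils::write.table(man, manifest_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}
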