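# Peptide dataset container and I/O.  A peptide_set is a data.frame
# with columns id, sequence and (optionally) label, where label is a
# factor with levels c("negative", "positive"); "positive" is the class
# of interest throughout the package.

#' Construct a validated peptide dataset
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of sequences over the 20 standard
#'   amino acids (case-insensitive; stored uppercase).
#' @param label Optional class labels; anything coercible to
#'   c("negative","positive") (also accepts 0/1, "neg"/"pos", logical).
#' @param name Dataset name carried as an attribute.
#' @param mode "strict" rejects sequences with non-standard residues
#'   (B, J, O, U, X, Z, ...); "lenient" drops them with a warning.
#' @return A `peptide_set` data.frame with columns id, sequence and,
#'   when labels were given, label.
#' @export
peptide_set <- function(id, sequence, label = NULL, name = "peptides",
                        mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) stop("id and sequence lengths differ")
  if (anyDuplicated(id)) stop("duplicate ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (!is.null(label) && length(label) != length(id))
    stop("label length differs from id length")

  if (any(!nzchar(sequence)))
    stop("empty sequence for id(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  bad <- !vapply(sequence, .valid_sequence, logical(1), USE.NAMES = FALSE)
  if (any(bad)) {
    offending <- vapply(sequence[bad], .offending_chars, character(1),
                        USE.NAMES = FALSE)
    msg <- paste0(id[bad], " (", offending, ")", collapse = "; ")
    if (mode == "strict")
      stop("invalid residues outside the 20-letter alphabet: ", msg)
    warning("dropping ", sum(bad), " record(s) with invalid residues: ", msg)
    id <- id[!bad]; sequence <- sequence[!bad]
    if (!is.null(label)) label <- label[!bad]
  }
  if (length(id) == 0L) stop("empty dataset: no valid peptide records")

  ds <- data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
  if (!is.null(label)) ds$label <- .coerce_label(label)
  class(ds) <- c("peptide_set", "data.frame")
  attr(ds, "name") <- name
  ds
}

.valid_sequence <- function(s) {
  nchar(s) > 0L &&
    all(strsplit(s, "", fixed = TRUE)[[1]] %in% aa_alphabet())
}

.offending_chars <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(sort(unique(ch[!ch %in% aa_alphabet()])), collapse = ",")
}

.coerce_label <- function(label) {
  if (is.factor(label)) label <- as.character(label)
  if (is.logical(label)) label <- ifelse(label, "positive", "negative")
  if (is.numeric(label)) {
    stopifnot(all(label %in% c(0, 1)))
    label <- ifelse(label == 1, "positive", "negative")
  }
  label <- tolower(as.character(label))
  label[label %in% c("pos", "1", "true", "tip")] <- "positive"
  label[label %in% c("neg", "0", "false", "non-tip", "nontip")] <- "negative"
  if (!all(label %in% c("negative", "positive")))
    stop("labels must be coercible to positive/negative")
  factor(label, levels = c("negative", "positive"))
}

#' @export
print.peptide_set <- function(x, ...) {
  cat("peptide_set '", attr(x, "name"), "': ", nrow(x), " peptides",
      sep = "")
  if (!is.null(x$label)) {
    tb <- table(x$label)
    cat(" (", tb[["positive"]], " positive / ", tb[["negative"]],
        " negative)", sep = "")
  }
  cat("; lengths ", min(nchar(x$sequence)), "-", max(nchar(x$sequence)),
      "\n", sep = "")
  invisible(x)
}

#' Read peptides from a FASTA file
#'
#' @param path FASTA file path.
#' @param label Optional single class tag applied to every record
#'   ("positive"/"negative"), or a vector of per-record labels.
#' @param mode Validation mode, see [peptide_set()].
#' @return A `peptide_set`.
#' @export
read_fasta <- function(path, label = NULL, mode = c("strict", "lenient")) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty dataset: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (!is.null(label) && length(label) == 1L)
    label <- rep(label, length(seqs))
  peptide_set(ids, as.character(seqs), label = label,
              name = basename(path), mode = match.arg(mode))
}

#' Write peptides to a FASTA file
#'
#' @param ds A `peptide_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path) {
  writeLines(paste0(">", ds$id, "\n", ds$sequence), path)
  invisible(path)
}

#' Read peptides from a two-column TSV (id, sequence)
#'
#' @inheritParams read_fasta
#' @param path TSV path with a header line naming columns id, sequence
#'   (a third `label` column is honoured when present).
#' @return A `peptide_set`.
#' @export
read_peptide_tsv <- function(path, label = NULL, mode = c("strict", "lenient")) {
  if (!file.exists(path)) stop("cannot read TSV file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence") %in% names(tab)))
    stop("TSV must have columns 'id' and 'sequence'")
  if (is.null(label) && "label" %in% names(tab)) label <- tab$label
  if (!is.null(label) && length(label) == 1L) label <- rep(label, nrow(tab))
  peptide_set(tab$id, tab$sequence, label = label, name = basename(path),
              mode = match.arg(mode))
}

#' Combine peptide datasets
#' @param ... `peptide_set` objects (ids must stay unique).
#' @param name Name of the combined set.
#' @return A `peptide_set`.
#' @export
combine_peptide_sets <- function(..., name = "combined") {
  parts <- list(...)
  ids <- unlist(lapply(parts, `[[`, "id"))
  seqs <- unlist(lapply(parts, `[[`, "sequence"))
  labs <- lapply(parts, `[[`, "label")
  label <- if (all(!vapply(labs, is.null, logical(1))))
    unlist(lapply(labs, as.character)) else NULL
  peptide_set(ids, seqs, label = label, name = name)
}

#' Remove exact duplicate sequences
#'
#' The first occurrence of each sequence is kept.  Duplicated sequences
#' that occur with conflicting labels are removed entirely (all
#' occurrences) and reported with a warning, since such records carry no
#' usable supervision.
#'
#' @param ds A `peptide_set`.
#' @return A deduplicated `peptide_set`, original order preserved.
#' @export
deduplicate <- function(ds) {
  stopifnot(inherits(ds, "peptide_set"))
  keep <- !duplicated(ds$sequence)
  if (!is.null(ds$label)) {
    nlab <- tapply(as.character(ds$label), ds$sequence,
                   function(l) length(unique(l)))
    conflicted <- names(nlab)[nlab > 1L]
    if (length(conflicted)) {
      warning(length(conflicted),
              " sequence(s) with conflicting labels removed: ",
              paste(head(conflicted, 5L), collapse = ", "))
      keep <- keep & !(ds$sequence %in% conflicted)
    }
  }
  out <- ds[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  rownames(out) <- NULL
  class(out) <- c("peptide_set", "data.frame")
  attr(out, "name") <- attr(ds, "name")
  out
}

#' Stratified random train/test split
#'
#' Each class is split independently: `round(n_class * train_fraction)`
#' samples (at least 1, at most n_class - 1) go to the training side.
#' With 133 positives and 287 negatives at fraction 0.8 this yields the
#' 106/230 training composition used for a benchmark of this size.
#'
#' @param ds A labeled `peptide_set` with both classes present.
#' @param train_fraction Real in (0, 1).
#' @param seed Integer seed; same seed, same partition.
#' @return List with elements `train` and `test` (both `peptide_set`s).
#' @export
split_dataset <- function(ds, train_fraction, seed = 1L) {
  stopifnot(inherits(ds, "peptide_set"), !is.null(ds$label),
            train_fraction > 0, train_fraction < 1)
  if (nlevels(droplevels(ds$label)) < 2L)
    stop("both classes must be present to split")
  rng <- .local_rng(seed)
  take <- logical(nrow(ds))
  for (cl in levels(ds$label)) {
    idx <- which(ds$label == cl)
    n_tr <- round(length(idx) * train_fraction)
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    if (n_tr < 1L || n_tr >= length(idx))
      stop("train fraction leaves class '", cl, "' empty on one side")
    take[rng(function() sample(idx, n_tr))] <- TRUE
  }
  out <- function(rows, tag) {
    d <- ds[rows, , drop = FALSE]
    rownames(d) <- NULL
    class(d) <- c("peptide_set", "data.frame")
    attr(d, "name") <- paste0(attr(ds, "name"), "_", tag)
    d
  }
  list(train = out(which(take), "train"), test = out(which(!take), "test"))
}

# run `f` under a private RNG state seeded with `seed`, restoring the
# caller's state afterwards; returns f's value.  Used everywhere a seed
# argument is documented so global RNG state never leaks in or out.
.local_rng <- function(seed) {
  force(seed)
  function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    f()
  }
}

# convenience wrapper: evaluate expr under seed-local RNG
.with_seed <- function(seed, expr) {
  rng <- .local_rng(seed)
  rng(function() expr)
}
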