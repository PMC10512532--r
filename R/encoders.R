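# Encoder registry: one fixed-dimension feature matrix per encoder.

#' Names of the ten feature encoders
#'
#' Six sequence descriptors (AAC, APAAC, DDE, DPC, PCP, PAAC) and four
#' keyed substructure fingerprints (Estate, FP4, MACCS, PubChem).
#' @return Character vector of length 10.
#' @export
encoder_names <- function() {
  c("AAC", "APAAC", "DDE", "DPC", "PCP", "PAAC",
    "Estate", "FP4", "MACCS", "PubChem")
}

#' Fixed output dimension of an encoder
#' @param encoder Encoder name, see [encoder_names()].
#' @return Integer dimension.
#' @export
encoder_dim <- function(encoder) {
  encoder <- match.arg(encoder, encoder_names())
  switch(encoder,
         AAC = 20L, APAAC = 22L, DDE = 400L, DPC = 400L, PCP = 11L,
         PAAC = 21L, Estate = 79L, FP4 = 307L, MACCS = 166L,
         PubChem = 881L)
}

#' Encode a peptide dataset with one encoder
#'
#' @param ds A `peptide_set`.
#' @param encoder Encoder name, see [encoder_names()].
#' @param ... Passed to the underlying encoder (e.g. `lambda`, `w` for
#'   PAAC/APAAC, `props` for PCP).
#' @return Numeric matrix, one row per peptide (rownames = ids), one
#'   named column per feature; `attr(, "encoder")` records the encoder.
#' @export
encode_features <- function(ds, encoder, ...) {
  stopifnot(inherits(ds, "peptide_set"))
  encoder <- match.arg(encoder, encoder_names())
  if (encoder %in% c("Estate", "FP4", "MACCS", "PubChem")) {
    m <- encode_fingerprint(ds, encoder)
    rownames(m) <- ds$id
  } else {
    f <- switch(encoder, AAC = encode_aac, APAAC = encode_apaac,
                DDE = encode_dde, DPC = encode_dpc, PCP = encode_pcp,
                PAAC = encode_paac)
    rows <- lapply(ds$sequence, f, ...)
    m <- do.call(rbind, rows)
    rownames(m) <- ds$id
  }
  if (ncol(m) != encoder_dim(encoder))
    stop("internal: ", encoder, " produced ", ncol(m), " columns")
  storage.mode(m) <- "double"
  attr(m, "encoder") <- encoder
  m
}

#' Write / read a feature matrix as CSV
#'
#' CSV layout: header of feature names, first column `id`.
#' @param m Feature matrix from [encode_features()].
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_feature_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
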