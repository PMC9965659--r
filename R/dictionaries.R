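#' Default token alphabets
#'
#' The package ships two fixed alphabets: a 64-character SMILES alphabet
#' covering the character set of canonicalized SMILES (organic-subset and
#' bracket-atom element letters, aromatic lowercase letters, ring-closure
#' digits, branch/bond/charge punctuation) and a 22-character protein
#' alphabet (the 20 standard amino acids plus X for unknown residues and U
#' for selenocysteine). Codes are assigned in insertion order starting at 1;
#' 0 is reserved for padding.
#'
#' @return Character vector of single-character tokens.
#' @export
smiles_alphabet <- function() {
  c(
    strsplit("0123456789", "")[[1]],
    c("(", ")", "[", "]", "=", "#", "-", "+", "@", "/", "\\", ".", "%", ":"),
    strsplit("ABCDEFGHIKLMNOPRSTUVWYZ", "")[[1]],
    strsplit("abcegilnoprstu", "")[[1]],
    c("*", "~", "$")
  )
}

#' @rdname smiles_alphabet
#' @export
protein_alphabet <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "U")
}

#' Build a token dictionary
#'
#' Maps each single character of `alphabet` to an integer code, assigned
#' 1..length(alphabet) in alphabet order. Code 0 is reserved for padding and
#' never assigned to a token.
#'
#' @param alphabet Character vector of unique single-character tokens.
#' @param modality `"smiles"` or `"protein"`; a tag carried by the dictionary
#'   so encoders can sanity-check that drug and protein inputs are not
#'   swapped.
#' @return An object of class `token_dictionary`: a named integer vector of
#'   codes with attributes `modality` and `size`.
#' @examples
#' d <- build_dictionary(c("A", "C", "G", "T"), "protein")
#' d[["C"]]  # 2
#' @export
build_dictionary <- function(alphabet, modality = c("smiles", "protein")) {
  modality <- match.arg(modality)
  alphabet <- as.character(alphabet)
  if (length(alphabet) == 0) {
    stop("alphabet must be non-empty", call. = FALSE)
  }
  if (any(nchar(alphabet) != 1L)) {
    stop("alphabet entries must be single characters", call. = FALSE)
  }
  dup <- alphabet[duplicated(alphabet)]
  if (length(dup) > 0) {
    stop("duplicate character in alphabet: ", paste(unique(dup), collapse = " "),
         call. = FALSE)
  }
  codes <- seq_along(alphabet)
  names(codes) <- alphabet
  structure(codes,
            modality = modality,
            size = length(alphabet),
            class = "token_dictionary")
}

#' @rdname build_dictionary
#' @export
default_dictionary <- function(modality = c("smiles", "protein")) {
  modality <- match.arg(modality)
  if (modality == "smiles") {
    build_dictionary(smiles_alphabet(), "smiles")
  } else {
    build_dictionary(protein_alphabet(), "protein")
  }
}

#' @export
print.token_dictionary <- function(x, ...) {
  cat(sprintf("<token_dictionary: %s, %d tokens>\n",
              attr(x, "modality"), attr(x, "size")))
  invisible(x)
}

#' Encode a string as a padded integer label vector
#'
#' Character-wise dictionary lookup, truncated to `max_len` and right-padded
#' with 0. The pre-truncation length (capped at `max_len`) is recorded so
#' downstream layers can mask padding.
#'
#' @param text A single string (SMILES or protein sequence).
#' @param dict A [build_dictionary()] object.
#' @param max_len Fixed output length (positive integer).
#' @param unknown What to do with characters absent from the dictionary:
#'   `"error"` (default) rejects them; `"zero"` maps them to the padding code
#'   0 with a warning.
#' @return An `encoded_sequence`: list with integer `codes` (length
#'   `max_len`), `original_length`, and `modality`.
#' @examples
#' d <- default_dictionary("protein")
#' enc <- encode_sequence("MKV", d, max_len = 5)
#' enc$codes
#' @export
encode_sequence <- function(text, dict, max_len,
                            unknown = c("error", "zero")) {
  unknown <- match.arg(unknown)
  stopifnot(inherits(dict, "token_dictionary"))
  if (length(max_len) != 1 || is.na(max_len) || max_len < 1) {
    stop("max_len must be a positive integer", call. = FALSE)
  }
  max_len <- as.integer(max_len)
  text <- as.character(text)
  if (length(text) != 1) stop("text must be a single string", call. = FALSE)
  chars <- if (nzchar(text)) strsplit(text, "")[[1]] else character(0)
  idx <- match(chars, names(dict))
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    if (unknown == "error") {
      stop("character(s) not in ", attr(dict, "modality"), " dictionary: ",
           paste(bad, collapse = " "), call. = FALSE)
    }
    warning("mapping unknown character(s) to padding code 0: ",
            paste(bad, collapse = " "), call. = FALSE)
  }
  codes <- unname(dict[idx])
  codes[is.na(codes)] <- 0L
  orig <- min(length(codes), max_len)
  codes <- codes[seq_len(orig)]
  codes <- c(as.integer(codes), integer(max_len - orig))
  structure(list(codes = codes,
                 original_length = orig,
                 modality = attr(dict, "modality")),
            class = "encoded_sequence")
}

#' Decode an integer label vector back to a string
#'
#' Inverse of [encode_sequence()] over in-dictionary, untruncated input:
#' padding (0) is dropped, every other code is replaced by its token.
#'
#' @param codes Integer vector or an `encoded_sequence`.
#' @param dict The dictionary used to encode.
#' @return A single string.
#' @export
decode_sequence <- function(codes, dict) {
  stopifnot(inherits(dict, "token_dictionary"))
  if (inherits(codes, "encoded_sequence")) codes <- codes$codes
  codes <- codes[codes != 0L]
  if (length(codes) == 0) return("")
  if (any(codes < 1 | codes > length(dict))) {
    stop("code outside dictionary range", call. = FALSE)
  }
  paste(names(dict)[codes], collapse = "")
}

#' Read / write a dictionary as two-column TSV
#'
#' Plain-text interchange format: UTF-8 TSV with columns `token` and `code`.
#'
#' @param path File path.
#' @param dict Dictionary to write.
#' @param modality Modality tag to attach on read.
#' @return `read_dictionary()` returns a `token_dictionary`;
#'   `write_dictionary()` returns `path` invisibly.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "token_dictionary"))
  readr::write_tsv(tibble::tibble(token = names(dict), code = as.integer(dict)),
                   path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path, modality = c("smiles", "protein")) {
  modality <- match.arg(modality)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    token = readr::col_character(), code = readr::col_integer()))
  if (any(duplicated(tab$token)) || any(duplicated(tab$code))) {
    stop("dictionary file has duplicate tokens or codes", call. = FALSE)
  }
  if (any(tab$code < 1)) stop("codes must be >= 1 (0 is padding)", call. = FALSE)
  codes <- tab$code
  names(codes) <- tab$token
  structure(codes, modality = modality, size = length(codes),
            class = "token_dictionary")
}

#' Read protein sequences from FASTA or return raw strings unchanged
#'
#' Accepts either a raw amino-acid string or a path to a single- or
#' multi-record FASTA file (headers are discarded).
#'
#' @param x A string: either a sequence or a path to a FASTA file.
#' @return Character vector of protein sequences.
#' @export
read_protein_input <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (file.exists(x)) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      return(unname(as.character(Biostrings::readAAStringSet(x))))
    }
    lines <- readLines(x, warn = FALSE)
    starts <- grep("^>", lines)
    if (length(starts) == 0) return(paste(trimws(lines), collapse = ""))
    ends <- c(starts[-1] - 1L, length(lines))
    return(vapply(seq_along(starts), function(i) {
      paste(trimws(lines[(starts[i] + 1L):ends[i]]), collapse = "")
    }, character(1)))
  }
  toupper(x)
}
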