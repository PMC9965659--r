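#' Read an affinity table
#'
#' Reads a delimited text file (CSV or TSV, sniffed from the extension) of
#' drug-target affinity records. The header must name the SMILES, protein
#' and affinity columns; names are remappable. An optional raw-Kd column (in
#' nM) can be converted on the fly with [kd_to_pkd()].
#'
#' @param path Path to a delimited file with a header row.
#' @param smiles_col,protein_col,affinity_col Column names (defaults
#'   `"smiles"`, `"protein"`, `"affinity"`).
#' @param kd_col Optional name of a raw Kd column in nM; when given and the
#'   affinity column is absent, affinities are computed as pKd.
#' @return A tibble with columns `smiles`, `protein`, `affinity` (plus
#'   `kd_nM` when present), one row per record in file order.
#' @export
read_affinity_table <- function(path, smiles_col = "smiles",
                                protein_col = "protein",
                                affinity_col = "affinity",
                                kd_col = NULL) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  need <- c(smiles_col, protein_col)
  has_aff <- affinity_col %in% names(raw)
  has_kd <- !is.null(kd_col) && kd_col %in% names(raw)
  if (!has_aff && !is.null(kd_col) && !has_kd) {
    stop("missing column: ", kd_col, call. = FALSE)
  }
  if (!has_aff && !has_kd) need <- c(need, affinity_col)
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    smiles = raw[[smiles_col]],
    protein = raw[[protein_col]]
  )
  .check_nonempty <- function(x, what) {
    bad <- which(is.na(x) | !nzchar(x))
    if (length(bad) > 0) {
      stop("empty ", what, " at row ", bad[1], call. = FALSE)
    }
  }
  .check_nonempty(out$smiles, "smiles")
  .check_nonempty(out$protein, "protein")
  .parse_num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      stop("non-numeric ", what, " at row ", bad[1], ": '", x[bad[1]], "'",
           call. = FALSE)
    }
    v
  }
  if (has_kd) {
    out$kd_nM <- .parse_num(raw[[kd_col]], "kd")
  }
  if (has_aff) {
    out$affinity <- .parse_num(raw[[affinity_col]], "affinity")
  } else {
    out$affinity <- kd_to_pkd(out$kd_nM)
  }
  out
}

#' @rdname read_affinity_table
#' @param data A data frame with columns `smiles`, `protein`, `affinity`.
#' @export
write_affinity_table <- function(data, path) {
  stopifnot(all(c("smiles", "protein", "affinity") %in% names(data)))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(dplyr::as_tibble(data), path, delim = delim)
  invisible(path)
}

#' Convert a dissociation constant in nM to pKd
#'
#' `pKd = -log10(Kd / 1e9)` with Kd expressed in nanomolar, the log-space
#' transform applied to Davis-style Kd measurements. Strictly decreasing in
#' Kd; one log-unit drop per tenfold Kd increase.
#'
#' @param kd_nM Positive dissociation constant(s) in nM.
#' @return pKd value(s): `kd_to_pkd(1) == 9`.
#' @examples
#' kd_to_pkd(c(1, 100, 1e9))  # 9 7 0
#' @export
kd_to_pkd <- function(kd_nM) {
  if (any(!is.finite(kd_nM)) || any(kd_nM <= 0)) {
    stop("Kd must be finite and > 0 (nM)", call. = FALSE)
  }
  -log10(kd_nM / 1e9)
}

#' Split affinity records into train / validation / test
#'
#' Seeded uniform shuffle followed by a contiguous partition, sized by
#' largest-remainder rounding of the fractions. The default fractions
#' (4/6, 1/6, 1/6) reproduce the conventional benchmark partition for this
#' task family to within one record.
#'
#' @param data Data frame of records (one row per drug-protein interaction).
#' @param fractions Positive fractions summing to 1, one per part.
#' @param seed Integer seed for the shuffle.
#' @param labels Part labels, default `c("train", "validation", "test")`.
#' @return The input tibble with a `split` factor column appended; the
#'   shuffle seed and fractions are carried as attributes.
#' @export
split_affinity <- function(data, fractions = c(4, 1, 1) / 6, seed = 1,
                           labels = c("train", "validation", "test")) {
  n <- nrow(data)
  if (length(labels) != length(fractions)) {
    labels <- if (length(fractions) == 3) c("train", "validation", "test")
              else paste0("part", seq_along(fractions))
  }
  if (any(fractions <= 0)) stop("fractions must be positive", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (n < length(fractions)) {
    stop("fewer records (", n, ") than split parts", call. = FALSE)
  }
  sizes <- largest_remainder_sizes(n, fractions)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  assign <- rep(labels, times = sizes)
  split <- character(n)
  split[perm] <- assign
  out <- dplyr::as_tibble(data)
  out$split <- factor(split, levels = labels)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "fractions") <- fractions
  out
}

#' Largest-remainder apportionment of n into parts
#'
#' @param n Total count.
#' @param fractions Positive fractions summing to 1.
#' @return Integer vector of part sizes summing to `n`; leftover units go to
#'   the parts with the largest fractional remainders (ties broken by part
#'   order).
#' @export
largest_remainder_sizes <- function(n, fractions) {
  exact <- n * fractions
  sizes <- floor(exact)
  rem <- exact - sizes
  leftover <- n - sum(sizes)
  if (leftover > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(leftover)]
    sizes[take] <- sizes[take] + 1
  }
  as.integer(sizes)
}

#' Assign k cross-validation folds over the non-test records
#'
#' Complements the fixed [split_affinity()] partition: the test part is kept
#' aside and the remaining records are dealt into `k` seeded folds, so
#' models can be trained k times with a rotating validation fold.
#'
#' @param data A tibble with a `split` column (from [split_affinity()]), or
#'   any data frame (all rows folded).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return The tibble with a `fold` integer column (`NA` for test rows).
#' @export
kfold_affinity <- function(data, k = 5, seed = 1) {
  out <- dplyr::as_tibble(data)
  pool <- if ("split" %in% names(out)) which(out$split != "test") else seq_len(nrow(out))
  if (length(pool) < k) stop("fewer records than folds", call. = FALSE)
  perm <- withr::with_seed(as.integer(seed), sample(pool))
  fold <- rep(NA_integer_, nrow(out))
  fold[perm] <- rep_len(seq_len(k), length(pool))
  out$fold <- fold
  out
}
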