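# Codon-level combinatorics of the standard genetic code: single-point
# mutation counts S_{i->j}, capacities M_i, fractions F_{i->j}, per-pair
# background means and path-graph expectations.

#' Canonical amino-acid one-letter symbols
#'
#' The 20 proteinogenic amino acids in alphabetical one-letter order. This is
#' the canonical label order used throughout the package for metric tables,
#' distance matrices and trees.
#'
#' @return Character vector of length 20.
#' @export
aa_symbols <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# RNA alphabet used internally; DNA input is transliterated on read.
RNA_BASES <- c("A", "C", "G", "U")

# Standard genetic code, RNA codons -> one-letter symbol, "*" for stop.
.standard_code <- function() {
  by_aa <- list(
    F = c("UUU", "UUC"),
    L = c("UUA", "UUG", "CUU", "CUC", "CUA", "CUG"),
    S = c("UCU", "UCC", "UCA", "UCG", "AGU", "AGC"),
    Y = c("UAU", "UAC"),
    C = c("UGU", "UGC"),
    W = "UGG",
    P = c("CCU", "CCC", "CCA", "CCG"),
    H = c("CAU", "CAC"),
    Q = c("CAA", "CAG"),
    R = c("CGU", "CGC", "CGA", "CGG", "AGA", "AGG"),
    I = c("AUU", "AUC", "AUA"),
    M = "AUG",
    T = c("ACU", "ACC", "ACA", "ACG"),
    N = c("AAU", "AAC"),
    K = c("AAA", "AAG"),
    V = c("GUU", "GUC", "GUA", "GUG"),
    A = c("GCU", "GCC", "GCA", "GCG"),
    D = c("GAU", "GAC"),
    E = c("GAA", "GAG"),
    G = c("GGU", "GGC", "GGA", "GGG"),
    `*` = c("UAA", "UAG", "UGA")
  )
  entries <- rep(names(by_aa), lengths(by_aa))
  names(entries) <- unlist(by_aa, use.names = FALSE)
  entries
}

#' Build a codon table
#'
#' Constructs a validated codon table, either the built-in standard genetic
#' code or a user-supplied alternative read from a two-column CSV
#' (`codon,symbol`). DNA codons (containing `T`) are transliterated to RNA.
#' Stop codons are labelled `"*"`.
#'
#' @param path Optional path to a `codon,symbol` CSV overriding the standard
#'   code. Symbols must be the 20 canonical one-letter codes plus `"*"`.
#' @return An object of class `codon_table`: a named character vector mapping
#'   the 64 RNA codons to amino-acid symbols, with attributes `by_aa` (codon
#'   sets per amino acid) and `n_codons` (degeneracy per amino acid).
#' @examples
#' code <- codon_table()
#' codons_for("W", code)
#' @export
codon_table <- function(path = NULL) {
  if (is.null(path)) {
    entries <- .standard_code()
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("codon table CSV needs columns codon,symbol")
    codons <- toupper(chartr("T", "U", as.character(df[[1L]])))
    entries <- as.character(df[[2L]])
    names(entries) <- codons
  }
  validate_codon_table(entries)
}

validate_codon_table <- function(entries) {
  codons <- names(entries)
  if (length(entries) != 64L || anyDuplicated(codons))
    stop("codon table must contain exactly the 64 distinct codons")
  ok <- grepl("^[ACGU]{3}$", codons)
  if (!all(ok))
    stop("invalid codon(s): ", paste(codons[!ok], collapse = ", "))
  bad_sym <- setdiff(unique(entries), c(aa_symbols(), "*"))
  if (length(bad_sym))
    stop("unknown amino-acid symbol(s): ", paste(bad_sym, collapse = ", "))
  sense <- entries[entries != "*"]
  if (length(sense) != 61L)
    stop("expected 61 sense codons, got ", length(sense))
  missing_aa <- setdiff(aa_symbols(), unique(sense))
  if (length(missing_aa))
    stop("amino acid(s) with no codon: ", paste(missing_aa, collapse = ", "))
  by_aa <- split(names(sense), factor(sense, levels = aa_symbols()))
  structure(entries,
            by_aa = by_aa,
            n_codons = lengths(by_aa),
            class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  n <- attr(x, "n_codons")
  cat("<codon_table> 61 sense codons, 3 stop codons\n")
  cat("degeneracy:", paste0(names(n), "=", n, collapse = " "), "\n")
  invisible(x)
}

.default_code_env <- new.env(parent = emptyenv())

# Built-in code, constructed once.
default_code <- function() {
  if (is.null(.default_code_env$code))
    .default_code_env$code <- codon_table()
  .default_code_env$code
}

.check_aa <- function(aa) {
  if (length(aa) != 1L || !aa %in% aa_symbols())
    stop("'", aa, "' is not a canonical amino-acid one-letter symbol")
  aa
}

.check_position <- function(position) {
  if (identical(position, "ALL") || identical(position, "all")) return("ALL")
  p <- suppressWarnings(as.integer(position))
  if (length(p) != 1L || is.na(p) || !p %in% 1:3)
    stop("position must be 1, 2, 3 or \"ALL\"")
  p
}

#' Codon set of an amino acid
#'
#' @param aa Canonical one-letter amino-acid symbol.
#' @param code A [codon_table()]; defaults to the standard genetic code.
#' @return Character vector of RNA codons encoding `aa`.
#' @export
codons_for <- function(aa, code = default_code()) {
  .check_aa(aa)
  attr(code, "by_aa")[[aa]]
}

#' Stop codons of a codon table
#'
#' @inheritParams codons_for
#' @return Character vector of stop codons (UAA, UAG, UGA for the standard
#'   code).
#' @export
stop_codons <- function(code = default_code()) {
  names(code)[code == "*"]
}

# Position (1..3) at which two codons differ, or NA if not exactly one.
.diff_position <- function(c1, c2) {
  d <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (length(d) == 1L) d else NA_integer_
}

# 20 x 20 x 3 array of single-point mutation counts between amino acids,
# entry [i, j, p] = number of codon pairs (c in C_i, c' in C_j) differing at
# exactly position p. Stops never participate. Cached per code.
.count_array <- function(code = default_code()) {
  key <- paste(code, collapse = "")
  cache <- attr(code, ".counts", exact = TRUE)
  if (!is.null(cache)) return(cache)
  if (!is.null(.default_code_env$counts) &&
      identical(.default_code_env$counts_key, key))
    return(.default_code_env$counts)
  sense <- names(code)[code != "*"]
  aa <- unname(code[sense])
  chars <- do.call(rbind, strsplit(sense, ""))
  n <- length(sense)
  arr <- array(0L, dim = c(20L, 20L, 3L),
               dimnames = list(aa_symbols(), aa_symbols(), NULL))
  ai <- match(aa, aa_symbols())
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      neq <- chars[i, ] != chars[j, ]
      if (sum(neq) == 1L && ai[i] != ai[j]) {
        p <- which(neq)
        arr[ai[i], ai[j], p] <- arr[ai[i], ai[j], p] + 1L
        arr[ai[j], ai[i], p] <- arr[ai[j], ai[i], p] + 1L
      }
    }
  }
  .default_code_env$counts <- arr
  .default_code_env$counts_key <- key
  arr
}

#' Single-point mutation count between two amino acids
#'
#' Counts codon pairs `(c, c')`, with `c` encoding `ai` and `c'` encoding
#' `aj`, that differ at exactly one nucleotide (restricted to one codon
#' position unless `position = "ALL"`). Substitutions to or from stop codons
#' are never counted. The count is symmetric in `(ai, aj)`.
#'
#' @param ai,aj Distinct canonical amino-acid symbols.
#' @param position Codon position `1`, `2`, `3`, or `"ALL"` (default).
#' @inheritParams codons_for
#' @return Nonnegative integer count `S`.
#' @examples
#' count_single_point("K", "N")       # 4, all at position 3
#' count_single_point("W", "M")       # 0
#' @export
count_single_point <- function(ai, aj, position = "ALL",
                               code = default_code()) {
  .check_aa(ai); .check_aa(aj)
  if (ai == aj)
    stop("ai and aj must differ: synonymous changes are out of scope")
  p <- .check_position(position)
  arr <- .count_array(code)
  if (identical(p, "ALL")) sum(arr[ai, aj, ]) else arr[ai, aj, p]
}

#' Mutation capacity of an amino acid
#'
#' Total number of possible single-nucleotide substitutions across the codons
#' of `ai`: `9 * n_i` over all positions (each of 3 sites can mutate to 3
#' alternative bases), or `3 * n_i` for a single position. Capacity is defined
#' purely from codon degeneracy; substitutions creating stop codons are still
#' counted in the denominator.
#'
#' @inheritParams count_single_point
#' @return Positive integer capacity `M`.
#' @export
mutation_capacity <- function(ai, position = "ALL", code = default_code()) {
  .check_aa(ai)
  p <- .check_position(position)
  n_i <- attr(code, "n_codons")[[ai]]
  if (identical(p, "ALL")) 9L * n_i else 3L * n_i
}

#' Fraction of single-point mutations from one amino acid to another
#'
#' `F_{i->j} = S_{i->j} / M_i`: the probability that a random single-point
#' mutation in a codon of `ai` yields a codon of `aj`. Generally asymmetric
#' because capacities differ.
#'
#' @inheritParams count_single_point
#' @return Real in `[0, 1]`.
#' @examples
#' mutation_fraction("L", "F")  # 6/54
#' mutation_fraction("F", "L")  # 6/18
#' @export
mutation_fraction <- function(ai, aj, position = "ALL",
                              code = default_code()) {
  count_single_point(ai, aj, position, code) /
    mutation_capacity(ai, position, code)
}

#' All pairwise single-point mutation statistics
#'
#' Tabulates, for every ordered pair of distinct amino acids, the mutation
#' count `S`, capacity `M`, fraction `F = S/M`, and a `has_path` flag marking
#' pairs connected by at least one single-point mutation (pairs without any
#' are excluded from scatter analyses of fraction versus complexity
#' distance).
#'
#' @inheritParams count_single_point
#' @return A data frame with columns `source`, `target`, `position`, `count`,
#'   `capacity`, `fraction`, `has_path`.
#' @export
mutation_pairs <- function(position = "ALL", code = default_code()) {
  p <- .check_position(position)
  arr <- .count_array(code)
  S <- if (identical(p, "ALL")) arr[, , 1L] + arr[, , 2L] + arr[, , 3L]
       else arr[, , p]
  aa <- aa_symbols()
  idx <- which(row(S) != col(S), arr.ind = TRUE)
  n_i <- attr(code, "n_codons")[aa[idx[, 1L]]]
  cap <- if (identical(p, "ALL")) 9L * n_i else 3L * n_i
  data.frame(source = aa[idx[, 1L]],
             target = aa[idx[, 2L]],
             position = if (identical(p, "ALL")) "ALL" else p,
             count = S[idx],
             capacity = as.integer(cap),
             fraction = S[idx] / cap,
             has_path = S[idx] > 0L,
             stringsAsFactors = FALSE)
}

#' Symmetric single-point mutation count matrix
#'
#' @inheritParams mutation_pairs
#' @return 20 x 20 symmetric integer matrix of counts `S`, zero diagonal.
#' @export
mutation_count_matrix <- function(position = "ALL", code = default_code()) {
  p <- .check_position(position)
  arr <- .count_array(code)
  if (identical(p, "ALL")) arr[, , 1L] + arr[, , 2L] + arr[, , 3L]
  else arr[, , p]
}

#' Background per-pair mean mutation count
#'
#' The normative background rate `B(p)`: the mean, over the 190 unordered
#' amino-acid pairs, of the number of unordered codon pairs that differ only
#' at position `p` and encode different amino acids (stop codons excluded).
#' For the standard code these are 83/190, 88/190 and 25/190 at positions
#' 1-3 (printed as 0.44, 0.46, 0.13 at two decimals).
#'
#' The `"per_aa"` variant is the literal per-amino-acid average of fractions,
#' `(1/20) sum_k sum_{j != k} S_{k->j}(p) / M_k(p)`; it does not reproduce the
#' per-pair values and is exposed only as a diagnostic.
#'
#' @inheritParams mutation_pairs
#' @param variant `"per_pair"` (normative) or `"per_aa"` (diagnostic literal
#'   per-amino-acid fraction average).
#' @return Nonnegative real.
#' @export
background_per_pair_mean <- function(position = "ALL",
                                     code = default_code(),
                                     variant = c("per_pair", "per_aa")) {
  variant <- match.arg(variant)
  p <- .check_position(position)
  S <- mutation_count_matrix(p, code)
  if (variant == "per_pair") {
    sum(S[upper.tri(S)]) / 190
  } else {
    cap <- vapply(aa_symbols(), mutation_capacity, numeric(1L),
                  position = p, code = code)
    mean(rowSums(S) / cap)
  }
}

#' Path-graph expected mutation total
#'
#' Expected per-position mutation total `E(p) = (N - 1) * B(p)` of a randomly
#' labelled path graph over the 20 amino acids (19 edges). By symmetry of
#' uniform random labelling this equals the expectation for any 20-node tree
#' topology, and matches the permutation-null means (19.600 in total, 8.300 /
#' 8.800 / 2.500 by position for the standard code).
#'
#' @inheritParams mutation_pairs
#' @return Nonnegative real.
#' @export
path_graph_expectation <- function(position = "ALL", code = default_code()) {
  19 * background_per_pair_mean(position, code)
}
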