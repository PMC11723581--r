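# Bit-string recognition model. MHC molecules and pathogen peptides are
# 16-bit strings; internally a string is stored as an integer code in
# [0, 65535] (bit 1 of the string is the least significant bit), with
# conversion helpers for the "0100..." text form.

BITSTRING_LENGTH <- 16L

#' Convert between 16-bit strings and integer codes
#'
#' Bit strings are stored internally as integers in \[0, 65535\]; the text
#' form is a 16-character string of 0s and 1s, first character = bit 1.
#'
#' @param x Character vector of 16-character 01-strings (`bitstring_to_code`)
#'   or integer vector of codes (`code_to_bitstring`).
#' @return Integer codes, or 16-character strings.
#' @examples
#' bitstring_to_code("1000000000000000")  # 1
#' code_to_bitstring(3L)                  # "1100000000000000"
#' @export
bitstring_to_code <- function(x) {
  if (!is.character(x) || any(nchar(x) != BITSTRING_LENGTH) ||
      any(grepl("[^01]", x))) {
    stop("bit strings must be 16-character strings of 0s and 1s")
  }
  vapply(strsplit(x, ""), function(b) {
    sum(as.integer(b) * 2L^(0:(BITSTRING_LENGTH - 1L)))
  }, numeric(1)) |> as.integer()
}

#' @rdname bitstring_to_code
#' @export
code_to_bitstring <- function(x) {
  if (any(x < 0) || any(x > 65535) || any(x != round(x))) {
    stop("codes must be integers in [0, 65535]")
  }
  vapply(as.integer(x), function(code) {
    paste(bitwAnd(bitwShiftR(code, 0:(BITSTRING_LENGTH - 1L)), 1L),
          collapse = "")
  }, character(1))
}

#' Longest consecutive match between MHC and peptide
#'
#' The match statistic of the bit-string model: align the MHC bit-string and
#' the peptide bit-string position by position (no shifting) and return the
#' length of the longest run of agreeing positions.
#'
#' @param mhc,peptide 16-character 01-strings or integer codes in
#'   \[0, 65535\].
#' @return Integer match length L in \[0, 16\].
#' @examples
#' max_match_length("1111000011110000", "1111111111110000")  # 8
#' @export
max_match_length <- function(mhc, peptide) {
  mhc <- as_bit_code(mhc)
  peptide <- as_bit_code(peptide)
  agree <- bitwNot_16(bitwXor(mhc, peptide))
  best <- run <- 0L
  for (i in 0:(BITSTRING_LENGTH - 1L)) {
    if (bitwAnd(bitwShiftR(agree, i), 1L) == 1L) {
      run <- run + 1L
      if (run > best) best <- run
    } else {
      run <- 0L
    }
  }
  best
}

as_bit_code <- function(x) {
  if (is.character(x)) return(bitstring_to_code(x))
  if (length(x) != 1L || x < 0 || x > 65535 || x != round(x)) {
    stop("expected a single 16-bit string or integer code in [0, 65535]")
  }
  as.integer(x)
}

bitwNot_16 <- function(x) bitwAnd(bitwNot(x), 65535L)

#' Peptide detection probability
#'
#' Logistic probability that an MHC molecule detects a peptide given their
#' longest consecutive match length `L`:
#' `D(L) = 1 / (1 + exp(a * (v - L)))`. `v` is the match length giving a 50%
#' detection chance (the bit-string model's virulence) and `a` the logistic
#' steepness. The default `a = log(9)` puts detection at 10% one match short
#' of `v` and 90% one match beyond it.
#'
#' @param L Match length(s).
#' @param v Virulence: match length for 50% detection.
#' @param a Steepness of the logistic (> 0); default `log(9)`.
#' @return Detection probability in (0, 1).
#' @examples
#' detection_probability(6, v = 7)  # 0.1
#' @export
detection_probability <- function(L, v, a = log(9)) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop("'a' must be a single positive number")
  }
  stats::plogis(a * (L - v))
}

#' Efficiency of an MHC allele against one pathogen
#'
#' A pathogen is countered if at least one of its `npep` peptides is
#' detected, so the efficiency is one minus the product of the per-peptide
#' miss probabilities.
#'
#' @param mhc MHC allele: 16-character 01-string or integer code.
#' @param peptides Peptides of the pathogen: character vector of 01-strings
#'   or integer codes (length `npep >= 1`).
#' @param v Virulence.
#' @param a Logistic steepness; default `log(9)`.
#' @return Efficiency in (0, 1).
#' @examples
#' # two peptides each detected with probability 0.5 -> 0.75
#' @export
pathogen_efficiency <- function(mhc, peptides, v, a = log(9)) {
  if (length(peptides) == 0L) stop("a pathogen needs at least one peptide")
  L <- vapply(peptides, function(p) max_match_length(mhc, p), integer(1))
  # stable 1 - prod(1 - D): stays positive even when every D underflows
  -expm1(sum(log1p(-detection_probability(L, v, a))))
}

#' Per-pathogen efficiency vector of a bit-string allele
#'
#' @param mhc MHC allele (string or code).
#' @param pathogens Pathogen set as returned by [random_pathogens()]: a list
#'   with element `peptides`, an `m x npep` integer matrix of peptide codes.
#' @return Numeric vector of length `m`.
#' @export
bitstring_efficiency_vector <- function(mhc, pathogens) {
  pep <- pathogens$peptides
  vapply(seq_len(nrow(pep)), function(k) {
    pathogen_efficiency(mhc, pep[k, ], pathogens$v, pathogens$a)
  }, numeric(1))
}

#' Random pathogen set for the bit-string model
#'
#' Draws `m` pathogens with `npep` independent uniform random 16-bit peptides
#' each (duplicates permitted). Uses the current R random number stream.
#'
#' @param m Number of pathogens (>= 1).
#' @param npep Peptides per pathogen (>= 1).
#' @param v Virulence stored with the set.
#' @param a Logistic steepness stored with the set; default `log(9)`.
#' @return List with elements `peptides` (`m x npep` integer matrix of
#'   codes), `v`, and `a`.
#' @export
random_pathogens <- function(m, npep, v, a = log(9)) {
  if (m < 1 || npep < 1) stop("'m' and 'npep' must be >= 1")
  codes <- sample.int(65536L, m * npep, replace = TRUE) - 1L
  list(peptides = matrix(codes, nrow = m, ncol = npep), v = v, a = a)
}

#' Mutate a bit-string allele
#'
#' Flips one uniformly chosen bit of the 16-bit string.
#'
#' @param mhc MHC allele (string or code).
#' @return Mutated allele, in the same representation as the input.
#' @export
mutate_bitstring <- function(mhc) {
  code <- as_bit_code(mhc)
  bit <- sample.int(BITSTRING_LENGTH, 1L) - 1L
  out <- bitwXor(code, bitwShiftL(1L, bit))
  if (is.character(mhc)) code_to_bitstring(out) else out
}

#' Read / write bit-string pathogen sets as plain text
#'
#' Tab-separated text with one line per peptide:
#' `pathogen_index<TAB>16-character 01-string`. `v` and `a` are not stored in
#' the file and must be supplied on reading.
#'
#' @param pathogens Pathogen set (see [random_pathogens()]).
#' @param path File path.
#' @param v,a Recognition parameters to attach on reading.
#' @return `read_pathogens` returns a pathogen-set list.
#' @export
write_pathogens <- function(pathogens, path) {
  pep <- pathogens$peptides
  df <- data.frame(
    pathogen = rep(seq_len(nrow(pep)), each = ncol(pep)),
    peptide = code_to_bitstring(as.integer(t(pep)))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pathogens
#' @export
read_pathogens <- function(path, v, a = log(9)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("pathogen", "peptide"),
                          colClasses = c("integer", "character"))
  idx <- sort(unique(df$pathogen))
  if (!identical(idx, seq_along(idx))) stop("pathogen indices must be 1..m")
  npep <- unique(table(df$pathogen))
  if (length(npep) != 1L) stop("all pathogens must have the same number of peptides")
  codes <- bitstring_to_code(df$peptide[order(df$pathogen)])
  list(peptides = matrix(codes, nrow = length(idx), ncol = npep, byrow = TRUE),
       v = v, a = a)
}
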