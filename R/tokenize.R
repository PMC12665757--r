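#' Tokenize a peptide sequence string
#'
#' Splits a raw sequence string into residue tokens. A token is either one of
#' the 20 standard one-letter amino-acid codes or a bracketed non-standard
#' amino-acid (NSAA) token such as `"[dS]"` (D-serine) or
#' `"[K (eK-eK-yE-C20DA)]"` (a lipidated lysine). Whitespace between tokens is
#' ignored; whitespace inside brackets is preserved verbatim. A standard
#' letter immediately preceding an opening bracket is folded into the bracket
#' token (so `"K [(yE-C16)]"` and `"[K (yE-C16)]"` parse identically).
#'
#' @param x Character scalar, the raw sequence.
#' @return Character vector of tokens (class `pep_tokens`).
#' @examples
#' pep_tokenize("HSQGTFTSDYSKYLDSRRAQDFVQWLMNT")
#' pep_tokenize("AC[dS]D")
#' @export
pep_tokenize <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("`x` must be a single sequence string", call. = FALSE)
  }
  chars <- strsplit(x, "")[[1]]
  tokens <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == "[") {
      depth <- 1L
      j <- i + 1L
      while (j <= n && depth > 0L) {
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) {
        stop(sprintf("unbalanced brackets starting at position %d", i), call. = FALSE)
      }
      tok <- paste0(chars[i:(j - 1L)], collapse = "")
      if (grepl("^\\[\\s*\\(", tok)) {
        # side-chain-only annotation, e.g. "K [(yE-C16)]": fold the preceding
        # base letter into the bracket token
        if (length(tokens) == 0L || !(tokens[length(tokens)] %in% AA_STANDARD)) {
          stop(sprintf(
            "side-chain annotation %s at position %d has no preceding base residue",
            tok, i
          ), call. = FALSE)
        }
        base <- tokens[length(tokens)]
        tokens <- tokens[-length(tokens)]
        tok <- paste0("[", base, " ", sub("^\\[\\s*", "", tok))
      }
      if (is.na(token_base(tok))) {
        stop(sprintf("NSAA token %s has no valid base residue letter", tok), call. = FALSE)
      }
      tokens <- c(tokens, tok)
      i <- j
    } else if (ch == "]") {
      stop(sprintf("unbalanced closing bracket at position %d", i), call. = FALSE)
    } else if (ch %in% AA_STANDARD) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop(sprintf("illegal residue letter '%s' at position %d", ch, i), call. = FALSE)
    }
  }
  if (length(tokens) == 0L) stop("empty sequence", call. = FALSE)
  structure(tokens, class = "pep_tokens")
}

#' Serialize tokens back to a sequence string
#'
#' Inverse of [pep_tokenize()]: `pep_tokenize(pep_detokenize(s))` recovers `s`.
#'
#' @param tokens Character vector of residue tokens.
#' @return Character scalar.
#' @export
pep_detokenize <- function(tokens) {
  stopifnot(length(tokens) >= 1L)
  paste0(unclass(tokens), collapse = "")
}

#' Base residue letter of each token
#'
#' For a standard token this is the token itself; for a bracketed NSAA token
#' it is the first standard-residue capital letter inside the bracket (`"[dS]"`
#' has base `"S"`, `"[K (yE-C16)]"` has base `"K"`).
#'
#' @param tokens Character vector of tokens.
#' @return Character vector of single letters (`NA` if no valid base).
#' @export
token_base <- function(tokens) {
  vapply(unclass(tokens), function(tok) {
    if (tok %in% AA_STANDARD) return(tok)
    inner <- gsub("^\\[|\\]$", "", tok)
    # side-chain text in parentheses does not contribute the base letter
    inner <- gsub("\\([^)]*\\)", "", inner)
    caps <- regmatches(inner, gregexpr("[A-Z]", inner))[[1]]
    caps <- caps[caps %in% AA_STANDARD]
    if (length(caps) == 0L) NA_character_ else caps[1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Classify tokens as D-amino acids or lipidated residues
#'
#' A bracketed token whose inner text starts with a lower-case `d` directly
#' followed by a standard letter is a D-amino acid (`"[dS]"`). A bracketed
#' token containing an acyl-chain pattern (`C` followed by digits, e.g.
#' `yE-C16`, `C20DA`) is lipidated.
#'
#' @param tokens Character vector of tokens.
#' @return Logical vector.
#' @export
token_is_d <- function(tokens) {
  grepl("^\\[d[A-Z]\\]$", unclass(tokens))
}

#' @rdname token_is_d
#' @export
token_is_lipidated <- function(tokens) {
  grepl("C[0-9]+", unclass(tokens)) & grepl("^\\[", unclass(tokens))
}

#' @export
print.pep_tokens <- function(x, ...) {
  cat("<pep_tokens> length", length(x), "\n")
  cat(pep_detokenize(x), "\n")
  invisible(x)
}

# Tokenize a character vector into a list of pep_tokens
tokenize_all <- function(x) lapply(x, pep_tokenize)
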