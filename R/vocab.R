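## SMILES tokenization and vocabulary handling.
##
## The generator operates on token indices, not characters.  A token is
## one of: an organic-subset atom symbol (aromatic or aliphatic, with the
## two-letter halogens Cl/Br kept whole), a full bracketed atom
## expression "[...]", a bond symbol, a branch parenthesis, a ring-bond
## digit or "%NN" escape, or one of the two control tokens GO (start)
## and EOS (end).  Tokenization is lossless: re-joining the tokens
## reproduces the input string exactly.

GO_TOKEN <- "GO"
EOS_TOKEN <- "EOS"

.tok_two_letter <- c("Cl", "Br")
.tok_atoms <- c("B", "C", "N", "O", "P", "S", "F", "I",
                "b", "c", "n", "o", "p", "s")
.tok_bonds <- c("-", "=", "#", "$", ":", "/", "\\", ".")
.tok_control <- c("(", ")", as.character(0:9))

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the token alphabet used by the generator.
#' Multi-character units — the two-letter halogens, bracketed atom
#' expressions such as `[nH]` or `[C@@H]`, and two-digit ring closures
#' `%NN` — are kept as single tokens, so `paste(tokens, collapse = "")`
#' always reproduces the input.
#'
#' @param smiles A single non-empty SMILES string.
#' @return Character vector of token symbols.
#' @examples \dontrun{tokenize_smiles("C(Cl)Br")}
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in SMILES: ", smiles,
                      call. = FALSE)
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)])))
        stop("malformed %NN ring closure in SMILES: ", smiles, call. = FALSE)
      out <- c(out, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% .tok_two_letter) {
      out <- c(out, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% c(.tok_atoms, .tok_bonds, .tok_control)) {
      out <- c(out, ch)
      i <- i + 1L
    } else {
      stop("character cannot start a SMILES token: '", ch, "' in ", smiles,
           call. = FALSE)
    }
  }
  out
}

#' Category of a SMILES token
#'
#' @param tokens Character vector of token symbols.
#' @return Character vector: one of `"atom"`, `"bond"`,
#'   `"branch-or-ring-control"`, `"special"`.
#' @export
token_category <- function(tokens) {
  vapply(tokens, function(tk) {
    if (tk %in% c(GO_TOKEN, EOS_TOKEN)) "special"
    else if (tk %in% c(.tok_atoms, .tok_two_letter) || startsWith(tk, "["))
      "atom"
    else if (tk %in% .tok_bonds) "bond"
    else if (tk %in% .tok_control || startsWith(tk, "%"))
      "branch-or-ring-control"
    else stop("unknown token: ", tk, call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' Build a SMILES vocabulary from a corpus
#'
#' Collects the union of tokens observed in the corpus and pins the
#' control tokens GO and EOS at positions 1 and 2; the remaining tokens
#' are sorted bytewise so repeated builds (and corpus permutations)
#' yield identical vocabularies.
#'
#' @param corpus Character vector of SMILES strings.
#' @return An object of class `smiles_vocab` with elements `tokens`
#'   (ordered symbols) and `index` (named integer positions, 1-based).
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(is.character(corpus))
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  seen <- unique(unlist(lapply(corpus, tokenize_smiles)))
  tokens <- c(GO_TOKEN, EOS_TOKEN, sort(setdiff(seen, c(GO_TOKEN, EOS_TOKEN)),
                                        method = "radix"))
  new_vocabulary(tokens)
}

#' Construct a vocabulary from an ordered token list
#' @param tokens Character vector; must contain `GO` and `EOS`.
#' @return A `smiles_vocab` object.
#' @export
new_vocabulary <- function(tokens) {
  stopifnot(is.character(tokens), !anyDuplicated(tokens),
            all(c(GO_TOKEN, EOS_TOKEN) %in% tokens),
            all(nzchar(tokens)), !any(grepl("\\s", tokens)))
  idx <- seq_along(tokens)
  names(idx) <- tokens
  structure(list(tokens = tokens, index = idx), class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("SMILES vocabulary:", length(x$tokens), "tokens\n")
  cat(" ", paste(utils::head(x$tokens, 30), collapse = " "),
      if (length(x$tokens) > 30) "...\n" else "\n")
  invisible(x)
}

#' @export
length.smiles_vocab <- function(x) length(x$tokens)

#' Encode a SMILES string as vocabulary indices
#'
#' @param smiles A single SMILES string.
#' @param vocab A `smiles_vocab`.
#' @return Integer vector of 1-based vocabulary positions (no GO/EOS).
#' @export
encode_smiles <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  toks <- tokenize_smiles(smiles)
  unknown <- setdiff(toks, vocab$tokens)
  if (length(unknown))
    stop("token(s) not in vocabulary: ", paste(unknown, collapse = " "),
         call. = FALSE)
  unname(vocab$index[toks])
}

#' Decode vocabulary indices back to a SMILES string
#'
#' Control tokens GO/EOS are dropped; decoding stops at the first EOS.
#'
#' @param indices Integer vector of 1-based vocabulary positions.
#' @param vocab A `smiles_vocab`.
#' @return A SMILES string (possibly empty).
#' @export
decode_tokens <- function(indices, vocab) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > length(vocab$tokens)))
    stop("index out of vocabulary range", call. = FALSE)
  toks <- vocab$tokens[indices]
  eos <- match(EOS_TOKEN, toks)
  if (!is.na(eos)) toks <- toks[seq_len(eos - 1L)]
  paste(toks[toks != GO_TOKEN], collapse = "")
}

#' Write / read a vocabulary file (one token per line, position = index)
#' @param vocab A `smiles_vocab`.
#' @param path File path.
#' @return `read_vocabulary` returns a `smiles_vocab`; `write_vocabulary`
#'   returns the path invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) new_vocabulary(readLines(path))

#' Read / write a SMILES corpus file (one SMILES per line, no header)
#' @param path File path.
#' @param smiles Character vector of SMILES.
#' @return `read_smi` returns a character vector.
#' @export
read_smi <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' @rdname read_smi
#' @export
write_smi <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}
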