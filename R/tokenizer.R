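# Byte-level BPE tokenizer for reaction SMILES.
#
# The base vocabulary contains every byte value, so any string encodes with
# zero unknown tokens; merges learned from the corpus compress frequent
# SMILES substrings into single tokens. Training is fully deterministic
# given the corpus (ties in pair frequency are broken lexicographically).

.SPECIALS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
.N_SPECIAL <- 5L
.N_BYTE <- 256L

.byte_token <- function(b) {
  printable <- b >= 33 & b <= 126
  ifelse(printable, vapply(b, function(x) rawToChar(as.raw(x)), ""),
         sprintf("<0x%02X>", b))
}

#' Train a byte-level BPE tokenizer
#'
#' @param corpus character vector of training strings (reaction / core
#'   SMILES).
#' @param vocab_size total vocabulary size including the 5 special tokens
#'   and the 256 byte-level base tokens (so `vocab_size > 261` learns
#'   merges).
#' @return a `pc_tokenizer`: vocabulary table (0-based dense ids), merge
#'   rules, special-token ids.
#' @export
train_tokenizer <- function(corpus, vocab_size = 288L) {
  if (!length(corpus) || all(!nzchar(corpus)))
    rlang::abort("empty tokenizer corpus")
  base_n <- .N_SPECIAL + .N_BYTE
  if (vocab_size <= base_n)
    rlang::abort(sprintf("vocab_size must exceed %d (specials + bytes)", base_n))

  token_text <- c(.SPECIALS, .byte_token(0:255))
  # sequences of 0-based ids
  seqs <- lapply(corpus, function(s) utf8ToInt(s) + .N_SPECIAL)
  merges <- matrix(integer(0), ncol = 2)

  while (length(token_text) < vocab_size) {
    pairs <- unlist(lapply(seqs, function(x) {
      if (length(x) < 2) return(character(0))
      paste(x[-length(x)], x[-1])
    }))
    if (!length(pairs)) break
    tab <- table(pairs)
    best_n <- max(tab)
    cand <- names(tab)[tab == best_n]
    # deterministic tie-break: lexicographically smallest merged token text
    cand_ids <- do.call(rbind, strsplit(cand, " "))
    cand_txt <- paste0(token_text[as.integer(cand_ids[, 1]) + 1L],
                       token_text[as.integer(cand_ids[, 2]) + 1L])
    pick <- order(cand_txt)[1]
    a <- as.integer(cand_ids[pick, 1]); b <- as.integer(cand_ids[pick, 2])
    new_id <- length(token_text)           # next 0-based id
    token_text <- c(token_text, paste0(token_text[a + 1L], token_text[b + 1L]))
    merges <- rbind(merges, c(a, b))
    seqs <- lapply(seqs, .apply_merge, a = a, b = b, new_id = new_id)
  }

  structure(list(
    vocab = tibble::tibble(id = seq_along(token_text) - 1L, token = token_text),
    merges = merges,
    specials = stats::setNames(seq_len(.N_SPECIAL) - 1L, .SPECIALS),
    vocab_size = length(token_text)
  ), class = "pc_tokenizer")
}

.apply_merge <- function(x, a, b, new_id) {
  n <- length(x)
  if (n < 2) return(x)
  hit <- which(x[-n] == a & x[-1] == b)
  if (!length(hit)) return(x)
  # skip overlapping hits (left to right)
  keep <- hit[c(TRUE, diff(hit) > 1)]
  drop <- logical(n)
  x[keep] <- new_id
  drop[keep + 1L] <- TRUE
  x[!drop]
}

#' Encode / decode with a trained tokenizer
#'
#' Encoding starts from bytes and applies the learned merges in training
#' order; decoding concatenates token texts, so
#' `decode(tok, encode(tok, s)) == s` for any string.
#'
#' @param tok a `pc_tokenizer`.
#' @param text a single string.
#' @param ids integer vector of 0-based token ids.
#' @return `tokenizer_encode`: 0-based token ids; `tokenizer_decode`: string.
#' @export
tokenizer_encode <- function(tok, text) {
  x <- utf8ToInt(text) + .N_SPECIAL
  if (nrow(tok$merges)) {
    for (k in seq_len(nrow(tok$merges))) {
      x <- .apply_merge(x, tok$merges[k, 1], tok$merges[k, 2],
                        .N_SPECIAL + .N_BYTE + k - 1L)
    }
  }
  x
}

#' @rdname tokenizer_encode
#' @export
tokenizer_decode <- function(tok, ids) {
  ids <- ids[!ids %in% tok$specials]
  paste(tok$vocab$token[ids + 1L], collapse = "")
}

#' Save / load a tokenizer as JSON
#'
#' @param tok a `pc_tokenizer`.
#' @param path JSON file path.
#' @export
write_tokenizer <- function(tok, path) {
  jsonlite::write_json(list(vocab = tok$vocab,
                            merges = unclass(tok$merges),
                            specials = as.list(tok$specials)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tokenizer
#' @export
read_tokenizer <- function(path) {
  j <- jsonlite::fromJSON(path)
  merges <- if (length(j$merges)) matrix(as.integer(unlist(j$merges)),
                                         ncol = 2, byrow = FALSE)
    else matrix(integer(0), ncol = 2)
  if (is.matrix(j$merges)) merges <- j$merges
  structure(list(vocab = tibble::as_tibble(j$vocab),
                 merges = merges,
                 specials = unlist(j$specials),
                 vocab_size = nrow(j$vocab)),
            class = "pc_tokenizer")
}

#' @export
print.pc_tokenizer <- function(x, ...) {
  cat(sprintf("<pc_tokenizer: vocab %d (%d merges)>\n",
              x$vocab_size, nrow(x$merges)))
  invisible(x)
}
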