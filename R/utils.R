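#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats glm binomial coef dhyper fisher.test pnorm rbeta rbinom rpois
#'   runif setNames wilcox.test confint.default
#' @importFrom utils head read.delim write.table
NULL

# Split text into sentences. Boundary rule: [.?!] (optionally followed by a
# closing quote/bracket) then whitespace, then an uppercase letter. Returns a
# tibble with the sentence text and its 0-based half-open span in `text`.
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble(sentence = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[.?!][\"')\\]]*[[:space:]]+(?=[A-Z])", text, perl = TRUE)[[1]]
  cut_after <- if (m[1] == -1) integer() else as.integer(m) + attr(m, "match.length") - 1L
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, nchar(text))
  keep <- starts <= ends
  starts <- starts[keep]
  ends <- ends[keep]
  sent <- substring(text, starts, ends)
  # trim trailing/leading whitespace but keep offsets aligned to the trimmed span
  lead <- nchar(sent) - nchar(sub("^[[:space:]]+", "", sent))
  trail <- nchar(sent) - nchar(sub("[[:space:]]+$", "", sent))
  starts <- starts + lead
  ends <- ends - trail
  keep <- starts <= ends
  tibble(
    sentence = substring(text, starts[keep], ends[keep]),
    start = starts[keep] - 1L,
    end = ends[keep]
  )
}

# Alphanumeric token spans (0-based half-open offsets) of `text`.
tokenize_spans <- function(text) {
  m <- gregexpr("[[:alnum:]]+(?:['-][[:alnum:]]+)*", text)[[1]]
  if (m[1] == -1) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  tibble(
    token = substring(text, start, start + len - 1L),
    start = start - 1L,
    end = start + len - 1L
  )
}

# Index (1-based) of the token whose span contains 0-based offset `pos`,
# falling back to the nearest token when `pos` lands between tokens.
token_index_at <- function(tokens, pos) {
  if (nrow(tokens) == 0L) return(NA_integer_)
  hit <- which(tokens$start <= pos & pos < tokens$end)
  if (length(hit) > 0L) return(hit[1])
  which.min(abs((tokens$start + tokens$end) / 2 - pos))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
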