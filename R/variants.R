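## Variant tokens ------------------------------------------------------------
##
## A variant is one scored difference from the reference sequence, held as a
## compact character token in full (1-based, 1..16569) coordinates:
##
##   "16093"      transition at 16093
##   "16111A"     substitution with derived base A (transversion unless the
##                base is the transition partner of the reference base)
##   "@16124"     back mutation: reversion to the ancestral state at 16124
##   "16166d"     deletion of position 16166
##   "16193.1C"   insertion of C after 16193 (first inserted base)
##
## HVS-I tables use the minus-16000 shorthand ("093 192" = 16093 + 16192);
## parsing adds the offset to positions below 1000.

.MT_LEN <- 16569L

.TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' Positions of variant tokens
#'
#' @param tokens character vector of canonical variant tokens.
#' @return integer vector of 1-based reference positions.
#' @export
variantPositions <- function(tokens) {
  if (length(tokens) == 0L) return(integer(0))
  as.integer(sub("^@?([0-9]+).*$", "\\1", tokens))
}

#' Kind of each variant token
#'
#' @param tokens character vector of canonical variant tokens.
#' @return character vector with values in \code{transition}, \code{transversion},
#'   \code{back_mutation}, \code{insertion}, \code{deletion}.
#' @export
variantKinds <- function(tokens) {
  vapply(tokens, function(tok) {
    if (startsWith(tok, "@")) return("back_mutation")
    if (grepl("^[0-9]+\\.[0-9]+[ACGT]$", tok)) return("insertion")
    if (grepl("^[0-9]+d$", tok)) return("deletion")
    if (grepl("^[0-9]+[ACGT]$", tok)) return("transversion")
    "transition"
  }, character(1), USE.NAMES = FALSE)
}

## order tokens by position, then lexicographically for stability
.sortTokens <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  tokens <- unique(tokens)
  tokens[order(variantPositions(tokens), tokens)]
}

## parse one raw token (parentheses already stripped); returns canonical token
.parseToken <- function(tok, offset) {
  raw <- tok
  back <- startsWith(tok, "@")
  if (back) tok <- substring(tok, 2L)
  del <- grepl("^[0-9]+(\\.[0-9]+)?d$", tok)
  if (del) tok <- sub("d$", "", tok)
  ins <- grepl("\\.", tok)
  base <- ""
  if (grepl("[A-Za-z]$", tok)) {
    base <- toupper(sub("^.*?([A-Za-z]+)$", "\\1", tok))
    tok <- sub("[A-Za-z]+$", "", tok)
    if (!base %in% c("A", "C", "G", "T"))
      stop("cannot parse variant token '", raw, "': unknown base '", base, "'")
  }
  if (ins) {
    parts <- strsplit(tok, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !grepl("^[0-9]+$", parts[1]) ||
        !grepl("^[0-9]+$", parts[2]))
      stop("cannot parse variant token '", raw, "'")
    pos <- as.integer(parts[1])
    idx <- as.integer(parts[2])
  } else {
    if (!grepl("^[0-9]+$", tok) || nchar(tok) == 0L)
      stop("cannot parse variant token '", raw, "'")
    pos <- as.integer(tok)
    idx <- NA_integer_
  }
  if (pos < 1000L) pos <- pos + as.integer(offset)
  if (pos < 1L || pos > .MT_LEN)
    stop("variant position ", pos, " (token '", raw,
         "') outside the reference range 1..", .MT_LEN)
  if (back) return(paste0("@", pos))
  if (del) return(paste0(pos, "d"))
  if (!is.na(idx)) {
    if (base == "") stop("insertion token '", raw, "' lacks an inserted base")
    return(paste0(pos, ".", idx, base))
  }
  paste0(pos, base)
}

## split a variant string into (token, unscored) honouring "(...)" groups
.tokenizeVariantString <- function(text, offset) {
  text <- gsub("\\(", " ( ", text)
  text <- gsub("\\)", " ) ", text)
  raw <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  raw <- raw[nzchar(raw)]
  tokens <- character(0)
  unscored <- integer(0)
  in_paren <- FALSE
  for (tok in raw) {
    if (tok == "(") {
      if (in_paren) stop("nested parentheses in variant string")
      in_paren <- TRUE
    } else if (tok == ")") {
      if (!in_paren) stop("unbalanced ')' in variant string")
      in_paren <- FALSE
    } else {
      canon <- .parseToken(tok, offset)
      if (in_paren) {
        unscored <- c(unscored, variantPositions(canon))
      } else {
        tokens <- c(tokens, canon)
      }
    }
  }
  if (in_paren) stop("unbalanced '(' in variant string")
  list(variants = .sortTokens(tokens), unscored = sort(unique(unscored)))
}

#' Format variants back to the minus-16000 table notation
#'
#' Inverse of \code{\link{parseVariantString}} on canonical haplotypes:
#' positions are sorted ascending, unscored positions are appended in a single
#' parenthesized group, and positions above the offset are printed minus the
#' offset, zero-padded to three digits.
#'
#' @param variants character vector of canonical variant tokens.
#' @param unscored integer vector of known-untyped positions.
#' @param offset integer subtracted from positions above it (default 16000);
#'   use 0 for whole-molecule coordinates.
#' @return a single variant string.
#' @export
formatVariantString <- function(variants, unscored = integer(0),
                                offset = 16000L) {
  fmt1 <- function(tok) {
    pos <- variantPositions(tok)
    if (offset > 0L && pos > offset) {
      short <- formatC(pos - offset, width = 3, flag = "0")
      sub(as.character(pos), short, tok, fixed = TRUE)
    } else tok
  }
  out <- vapply(.sortTokens(variants), fmt1, character(1), USE.NAMES = FALSE)
  if (length(unscored)) {
    u <- vapply(as.character(sort(unique(unscored))), fmt1, character(1),
                USE.NAMES = FALSE)
    out <- c(out, paste0("(", paste(u, collapse = " "), ")"))
  }
  paste(out, collapse = " ")
}

#' Score an aligned sequence against a reference
#'
#' Compares two pre-aligned sequences of equal length position by position and
#' returns the differences as canonical variant tokens in reference
#' coordinates. Substitutions are classified as transitions (A<->G, C<->T) or
#' transversions; alignment gaps produce insertion/deletion tokens. Internal
#' alignment is out of scope: inputs must already be aligned.
#'
#' @param seq,reference character strings or \code{Biostrings::DNAString}s of
#'   equal length (gaps as \code{-}).
#' @return character vector of canonical variant tokens.
#' @export
scoreAgainstReference <- function(seq, reference) {
  s <- toupper(as.character(seq))
  r <- toupper(as.character(reference))
  if (nchar(s) != nchar(r))
    stop("sequence (", nchar(s), ") and reference (", nchar(r),
         ") lengths differ; inputs must be pre-aligned")
  sv <- strsplit(s, "")[[1]]
  rv <- strsplit(r, "")[[1]]
  tokens <- character(0)
  refpos <- 0L
  ins_idx <- 0L
  for (i in seq_along(rv)) {
    rb <- rv[i]; sb <- sv[i]
    if (rb == "-") {                       # insertion relative to reference
      ins_idx <- ins_idx + 1L
      if (sb != "-")
        tokens <- c(tokens, paste0(max(refpos, 1L), ".", ins_idx, sb))
      next
    }
    refpos <- refpos + 1L
    ins_idx <- 0L
    if (sb == rb) next
    if (sb == "-") {
      tokens <- c(tokens, paste0(refpos, "d"))
    } else if (sb == "N") {
      next                                 # unscored base, not a variant
    } else if (identical(unname(.TRANSITION_PARTNER[rb]), sb)) {
      tokens <- c(tokens, as.character(refpos))
    } else {
      tokens <- c(tokens, paste0(refpos, sb))
    }
  }
  .sortTokens(tokens)
}
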