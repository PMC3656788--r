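#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dhyper phyper p.adjust pchisq pnorm rbinom rnbinom
#'   rnorm runif rlnorm sd hclust cutree as.dist coef predict setNames
#'   quantile median
#' @importFrom utils head tail write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be TRUE or FALSE", name)
  invisible(x)
}

.check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (strict && x <= min) .stopf("'%s' must be > %s", name, min)
  if (!strict && x < min) .stopf("'%s' must be >= %s", name, min)
  invisible(x)
}

DNA_BASES4 <- c("A", "C", "G", "T")

## integer codes 1..4 for A,C,G,T; NA for anything else (N etc.)
.encode_dna <- function(seq_char) {
  v <- strsplit(toupper(seq_char), "", fixed = TRUE)[[1L]]
  m <- match(v, DNA_BASES4)
  m
}

.revcomp <- function(seq_char) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_char)))
}

## deterministic child seed derivation; keeps results below .Machine$integer.max
.child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
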