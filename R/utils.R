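#' @importFrom methods new is validObject slot
#' @importFrom stats runif rmultinom setNames
#' @importFrom utils read.delim write.table head modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

## reverse complement for short plain-character motifs; vectorised over units
revcompBase <- function(x) chartr("ACGT", "TGCA", x)

revcompUnit <- function(unit) {
  vapply(unit, function(u) {
    paste(rev(strsplit(revcompBase(u), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## deterministic child seed from a master seed and a label; stays < 2^31
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 7919 + h * 104729 + 13) %% 2147483629)
}

isCountVector <- function(x, tol = 1e-6) {
  all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) <= tol)
}

## single-line structured log on stderr, used by the profilers and the CLI
sigLog <- function(stage, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0("[cancerSig] ", stage,
                if (length(kv))
                  paste0(" ", paste(names(kv), unlist(kv), sep = "=",
                                    collapse = " ")) else "")
  message(msg)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
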